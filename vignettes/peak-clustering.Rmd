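---
title: "Peak clustering for MEG group analysis: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peak clustering for MEG group analysis: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Why peaks

A beamformer maps a few hundred MEG channels onto tens of thousands of
voxels, so a volumetric image of source power is heavily redundant: sharp
and trustworthy near strong sources, very smooth everywhere else, with
side-lobes whose shape depends on dipole orientation rather than distance.
Voxelwise group tests inherit that structure — smooth maxima overlap across
participants and produce broad, sometimes disconnected group effects that
are features of the reconstruction, not of the brain. The peak-clustering
statistic discards everything except each participant's local maxima
(where beamformer estimates are reliable) and their rank order, and asks
one question: are the top-ranked peaks more tightly co-located across
participants than a random selection of each participant's peaks would be?

The null hypothesis is therefore *exchangeability of rank with respect to
location within each participant*. Nothing is assumed about image
smoothness, amplitude distributions, or spatial covariance; the test is
exact by permutation for any fixed peak count M.

## The procedure

1. **Peak extraction** (`find_local_maxima`). A voxel is a peak when it
   strictly exceeds its 18-connected in-mask neighbours (faces + edges of
   the 3×3×3 cube) — the `spm_max` rule, under which two maxima may sit a
   single non-maximal voxel apart. Neighbours outside the volume or mask
   are ignored, so edge maxima are reportable; plateaus are not maxima
   (strictness is the only deterministic reading of a neighbour rule).
   Peaks of the "wrong" sign are kept — ranking, not thresholding, drives
   the statistic — though `require_sign_consistent` can drop them.
2. **Smallest clusters** (`smallest_clusters`). The top-M peaks of all N
   participants are pooled and partitioned by k-means with k = M; after
   each assignment, every cluster is trimmed to at most one peak per
   participant, keeping the peak nearest the centroid (ties keep the
   better-ranked peak, rank being the method's ordering principle), and
   centroids are recomputed from the trimmed members. Over 30 iterations
   and 10 k-means++ restarts, the smallest trimmed cluster is recorded for
   every achieved participant count N′. Clusters reduced below 2 points
   are discarded. This is a search heuristic, not an exact minimiser —
   the exhaustive minimum is exponential in N — but the unit tests verify
   it attains the brute-force optimum on every small instance tried, and
   `restarts` lets a cautious user tighten it (recorded radii can only
   shrink as restarts grow).
3. **Ellipsoids** (`fit_ellipsoid`). Axes are the eigenvectors of the
   member-coordinate covariance (sample covariance, n−1); per-axis 95%
   radii are 1.959964 × the SD along each axis, the two-sided Gaussian 95%
   half-width. The Gaussian constant is a convention: it multiplies
   observed and null radii identically, so p-values are invariant to it.
   Cluster size is always compared by the **major radius**; volume is
   reported, never ranked on. With fewer than 3 distinct points the
   missing eigen-directions get radius 0.
4. **Null and p-value** (`build_null`, `p_value`). Each of K permutations
   shuffles ranks *within* each participant's full peak list (shuffling
   across participants would move locations between heads) and reruns the
   identical cluster search — same iterations, restarts and RNG stream —
   so observed and null statistics are exchangeable under H0.
   `p = (1 + #{r_null ≤ r_obs})/(K + 1)` avoids p = 0 and is monotone in
   the observed radius. Permutations that achieve no cluster of a given N′
   count as "larger than observed".
5. **Scanning M** (`peakclust`). Increasing M re-tests the same hypothesis
   on overlapping subsets; a genuinely new subset enters only when M
   doubles, giving the Bonferroni family `1 + log2(M_end/M_start)` and the
   corrected threshold `α/(1 + log2(M_end/M_start))` — 0.0094 for 2..40 at
   α = 0.05, invariant under common scaling of the bounds.

### Choosing M

The null significance radius R(M, N′) — the radius that 95% of chance
clusters exceed, i.e. the 5th percentile of the null major radii — falls
with M and rises with N′. Small M respects rank but tolerates loose
clusters; large M demands implausibly tight ones. `heuristic_J` scores the
trade-off as the distance `J = sqrt(M² + R²)` from the origin of the
(peak count, mm) plane and reports the minimising M per subgroup. The two
axes have different units, so the default weighting (1 peak ≡ 1 mm) is a
convention; both axis scales are exposed. J is a labelled heuristic, not
part of the inference: multiple-comparison control comes from the log2
correction, not from the knee.

### Reporting recurrent regions

One region typically yields significant ellipsoids over a range of M and
several N′. Spatial identity of "the same region" is not well defined for
overlapping ellipsoids, so `reported_regions` uses membership instead: two
significant clusters are merged when they share a member peak (same
participant, same location), and each merged region reports its largest-N′
cluster, ties broken by smallest major radius — preferring the finding
that speaks for the most participants, then the tightest one.

## The simulation study

`sim_config()` defaults encode the benchmark conditions: per participant a
single dipole at `N((52, −29, 13) mm, 5 mm SD iso)`, driven by a 40 Hz
sinusoid for 200 ms at 200 Hz sampling, active in 30 of 60 epochs, with
white sensor noise of density 10 fT/√Hz over an 80 Hz bandwidth (per-sample
SD 10·√80 ≈ 89.4 fT); images are LCMV pseudo-t volumes on a 10 mm grid;
groups are 20 draws of 8 participants from a pool of 10, analysed with
M = 5, and a finding within 20 mm of the seed centre is a hit.

Design points that were genuinely open:

* **Sensor geometry.** Exact commercial helmet coordinates are not
  reproducible from public sources, so the array is 275 radial
  magnetometers on a Fibonacci lattice over the upper hemisphere at 12 cm,
  around a 9 cm conducting sphere; axial gradiometers are approximated as
  radial magnetometers. The statistic consumes only peak locations, which
  depend weakly on the layout.
* **Forward model.** The conducting-sphere (Sarvas) solution, implemented
  directly; its radial projection is verified in the tests against the
  free-space Biot–Savart field, which is an independent formula because a
  spherical conductor's volume currents are radially silent. Radial
  dipoles and a central dipole produce zero field, as they must.
* **Orientation.** The benchmark tied orientation to a cortical mesh
  normal at the jittered location. Without a mesh, each participant's
  orientation is a fixed reference normal tilted by (location jitter)/25 mm
  — about 11° of scatter for a 5 mm jitter — then projected into the
  tangential plane (the sphere model is blind to the radial component).
  Location and orientation thus co-vary across participants, which is the
  property that matters.
* **Head placement.** MNI-like mm coordinates map to the head frame by a
  fixed translation (sphere centre at (0, −25, 15) mm). Hits and misses
  are measured in the same mm space, so the choice cancels.
* **Noise scale for pseudo-t.** The denominator uses σ²WᵀW with σ² the
  sensor noise variance; in simulations the known value can be passed, and
  the default estimates it from the control-state covariance diagonal. A
  variant with a factor-2 denominator exists in the literature; either
  constant rescales all voxels equally and leaves peak ranks — all the
  clustering consumes — unchanged.
* **Beamformer details.** Weights come from one covariance window spanning
  both states (the dual-covariance variant used by proprietary software for
  experimental data is out of scope); orientation is the generalized
  eigenvector of (HᵀC⁻¹H, HᵀC⁻²H) maximising output SNR; inversion is a
  pseudo-inverse with relative tolerance 1e-12 and **no regularization** by
  default (maximum spatial resolution, maximum peak count), with a
  `mu` option for Tikhonov loading as a fraction of mean sensor power.
* **Comparator.** `snpm_like_test` is a faithful-in-spirit reimplementation
  of the variance-smoothed one-sample permutation test, not a port:
  Gaussian variance smoothing (FWHM 25 mm by default; 6/12/24 mm are the
  usual experimental settings), sign-flip null (exhaustive when 2ⁿ fits the
  permutation budget), max-statistic FWE control, 18-neighbour maxima of
  supra-threshold voxels. The artefact being demonstrated — overlap of
  smooth side-lobes — does not depend on any implementation detail of the
  original tool.
* **Hit/miss bookkeeping.** Per-participant true locations differ within a
  group, so hits are measured to the *distribution centre* (52, −29, 13) by
  default (`hit_reference = "group_mean"` switches to the group's realized
  mean). The runner tests the full-group cluster (`n_min = group_size`),
  giving at most one candidate region per group and a natural ceiling of
  20 findings over 20 groups; `n_min` is exposed for subgroup analyses.

## The fixture generator

`make_fixture` emulates only the statistical structure the clustering layer
assumes: per participant, uniform decoy peaks in a brain-sized mm box,
plus — in a chosen fraction of participants — one true peak jittered around
a common centre with Gaussian SD and a rank drawn uniformly from
`1:true_rank_max`. Decoy values are i.i.d., so with `participation = 0`
rank is independent of location by construction and the rejection rate
measures pure type-I error. What the generator does *not* emulate:
spatially structured decoys (side-lobes co-varying across participants),
value–location dependence, or inhomogeneous peak density. Calibration and
power results on fixtures therefore validate the inference machinery, not
the method's behaviour on real beamformer output — that is what the
simulation pipeline is for.

## Numerical conventions

* Coordinates are mm in the image's declared world space throughout; voxel
  indices are 0-based internally and never exposed. No template-to-template
  conversion is ever attempted.
* Ranking ties (equal values) are resolved by stable sort order;
  trimming ties by better rank; k-means empty clusters keep their centroid.
* Non-finite voxels are treated as outside the mask; a constant image has
  no strict maxima and yields an empty peak list; an all-masked image is an
  error.
* Eigenvalues below 1e-12 of the leading one are treated as zero
  (degenerate ellipsoid directions).
* All randomness flows from user-supplied seeds: R's RNG drives the
  permutations, the fixture and MEG generators, and (through Rcpp's RNG
  scope) the compiled k-means++ seeding, so fixed seeds reproduce results
  bit for bit.

## Scale of the shipped checks

The test-suite and acceptance runs use deliberately modest problem sizes
chosen to exercise every code path at comfortable desk scale: brute-force
cluster enumeration at N = 3, M = 2 (8 subsets); calibration over 200
fixture replicates at K = 200 permutations; the simulation benchmark with
20 groups of 8 at K = 200 (tests) or K = 500 (acceptance script) and one
or two source magnitudes. Larger M ranges, pools and permutation counts
only sharpen the same quantities.

## Known limitations

* The cluster search is a heuristic; pathological configurations could in
  principle hide a smaller ellipsoid from both the observed and null
  searches (the comparison stays like-for-like, so validity is unaffected;
  sensitivity could suffer).
* The method needs the effect to produce a local maximum in most
  participants — sub-threshold effects that only emerge in a group average
  are invisible to it, and truly extended activations are reduced to their
  peaks.
* Subgroup findings (N′ < N) invite care: an effect in 6 of 10 heads is
  reported as exactly that, and readers should weigh it accordingly.
* The simulator covers one dipole in a sphere with white noise; correlated
  brain noise, multi-source scenes and realistic head models are out of
  scope, as is condition-label shuffling (a natural extension noted for
  future work).
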