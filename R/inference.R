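#' Randomly reassign ranks within each participant's peak list
#'
#' The permutation scheme behind the null distribution: each participant's
#' peak locations and values keep their pairing, but the ranks become a
#' uniform random permutation of that participant's full list. A subsequent
#' [top_m()] therefore draws a uniform random M-subset of the participant's
#' peaks; locations never move between participants.
#'
#' @param peaklists list of full (untruncated) [peak_list()] objects.
#' @return A list of peak lists with shuffled ranks.
#' @export
permute_ranks <- function(peaklists) {
  lapply(peaklists, function(pl) {
    P <- length(pl$value)
    if (P <= 1L) return(pl)
    ord <- sample.int(P)
    out <- pl
    out$loc_mm <- pl$loc_mm[ord, , drop = FALSE]
    out$value <- pl$value[ord]
    out$rank <- seq_len(P)
    out
  })
}

#' Permutation null distribution of cluster radii
#'
#' Runs `K` independent rank shufflings ([permute_ranks()]), each followed by
#' the same cluster search as the observed data ([smallest_clusters()] with
#' identical `m`, `iterations` and `restarts`), and stores the per-subgroup
#' minimum major radius of every permutation. This is the distribution of
#' cluster sizes expected when peak rank carries no spatial information.
#'
#' @inheritParams smallest_clusters
#' @param K number of permutations.
#' @return An object of class `null_distribution`: `radii` is a K x
#'   (subgroup sizes) matrix (NA when a permutation achieved no cluster of
#'   that size), columns named by N'.
#' @export
build_null <- function(peaklists, m, n_min, K = 500, iterations = 30,
                       restarts = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_part <- length(peaklists)
  sizes <- n_min:n_part
  radii <- matrix(NA_real_, nrow = K, ncol = length(sizes),
                  dimnames = list(NULL, as.character(sizes)))
  for (k in seq_len(K)) {
    cs <- smallest_clusters(permute_ranks(peaklists), m = m, n_min = n_min,
                            iterations = iterations, restarts = restarts)
    radii[k, ] <- cs$radii
  }
  structure(list(radii = radii, m = m, n_min = n_min, K = K,
                 n_participants = n_part),
            class = "null_distribution")
}

#' Permutation p-value for an observed cluster
#'
#' Uses the add-one estimator `p = (1 + #\{null radii <= observed\}) /
#' (K + 1)`, which never returns 0 and is monotone non-decreasing in the
#' observed major radius. Permutations in which no cluster of the relevant
#' subgroup size was achieved count as larger than any observed radius.
#'
#' @param observed an [fit_ellipsoid()] result (or a numeric major radius in
#'   mm, in which case `n` must be given).
#' @param null a [build_null()] result.
#' @param n subgroup size; defaults to `observed$n_participants`.
#' @return The permutation p-value in (0, 1].
#' @export
p_value <- function(observed, null, n = NULL) {
  stopifnot(inherits(null, "null_distribution"))
  if (inherits(observed, "ellipsoid")) {
    if (is.null(n)) n <- observed$n_participants
    observed <- observed$major_radius_mm
  }
  if (is.null(n)) stop("`n` is required when `observed` is a radius")
  key <- as.character(n)
  if (!key %in% colnames(null$radii))
    stop("null distribution has no entries for subgroup size ", n)
  r <- null$radii[, key]
  (1 + sum(r <= observed, na.rm = TRUE)) / (null$K + 1)
}

#' Corrected significance threshold for scanning a range of peak counts
#'
#' Testing the clustering hypothesis over M = `m_start` .. `m_end` re-tests
#' one null hypothesis on overlapping subsets of the data; an effectively
#' independent subset only enters each time the number of peaks doubles, so
#' the Bonferroni family size is `1 + log2(m_end / m_start)` and the
#' test-wise threshold is `alpha / (1 + log2(m_end / m_start))`. For the
#' conventional scan M = 2..40 at alpha 0.05 this gives 0.0094. The
#' threshold is invariant under scaling both bounds by the same factor.
#'
#' @param alpha family-wise error rate.
#' @param m_start,m_end first and last peak count scanned (`1 <= m_start <=
#'   m_end`).
#' @return The corrected test-wise significance level.
#' @export
corrected_alpha <- function(alpha = 0.05, m_start, m_end) {
  if (m_start < 1 || m_end < m_start)
    stop("need 1 <= m_start <= m_end")
  alpha / (1 + log2(m_end / m_start))
}

#' Null confidence-radius curve R(M, N')
#'
#' Extracts, from a [peakclust()] scan, the 95%-significance radius for
#' every scanned peak count M and subgroup size N': the radius a cluster
#' must beat to be significant at 0.05 uncorrected, i.e. the radius that
#' 95% of chance clusters exceed (the 5th percentile of the null
#' major-radius distribution). The curve falls with M (more peaks make
#' small clusters easy by chance) and rises with N'.
#'
#' @param scan a [peakclust()] result.
#' @return An object of class `heuristic_curve`: list with `m` (peak
#'   counts), `n` (subgroup sizes) and matrix `R` (length(m) x length(n),
#'   mm).
#' @export
heuristic_curve <- function(scan) {
  stopifnot(inherits(scan, "peakclust"))
  structure(list(m = scan$m_values, n = scan$n_values, R = scan$null_crit),
            class = "heuristic_curve")
}

#' Peak-count trade-off heuristic J
#'
#' Small M ties the analysis to peak rank but tolerates large chance
#' clusters (large null radius R); large M demands very tight clustering.
#' `J(M, N') = sqrt((ms * M)^2 + (rs * R(M, N'))^2)` measures the distance
#' of each point of the R-vs-M curve from the origin of the (peak count,
#' mm) plane; its minimiser per subgroup size marks the knee of the curve
#' and is a pragmatic default for M. The axis scalings `m_scale` and
#' `r_scale` are exposed because the two axes carry different units; the
#' default weighs 1 peak equal to 1 mm.
#'
#' @param curve a [heuristic_curve()], or a numeric matrix of null radii
#'   (rows = peak counts, columns = subgroup sizes).
#' @param m values of M matching the rows (taken from `curve` when it is a
#'   `heuristic_curve`).
#' @param m_scale,r_scale axis weights applied to M and R.
#' @return List with `J` (same shape as `R`) and `m_opt`, the minimising M
#'   per subgroup size.
#' @export
heuristic_J <- function(curve, m = NULL, m_scale = 1, r_scale = 1) {
  if (inherits(curve, "heuristic_curve")) {
    R <- curve$R
    m <- curve$m
  } else {
    R <- as.matrix(curve)
    if (is.null(m)) m <- seq_len(nrow(R))
  }
  stopifnot(length(m) == nrow(R))
  J <- sqrt((m_scale * m)^2 + (r_scale * R)^2)
  m_opt <- apply(J, 2, function(col) {
    if (all(is.na(col))) NA_real_ else m[which.min(col)]
  })
  list(J = J, m = m, m_opt = m_opt)
}
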