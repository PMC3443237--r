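#' Hit/miss benchmarking protocol for the two group methods
#'
#' Reproduces the simulation benchmark: for each source magnitude, a pool of
#' `pool_size` participants is simulated ([simulate_group()]) and beamformed
#' to pseudo-t images ([beamform_image()]); `n_groups` groups of
#' `group_size` images are drawn from the pool; each group is analysed with
#' the peak-clustering statistic (top `m` peaks, `K` rank-shuffling
#' permutations) and, optionally, the SnPM-style volumetric comparator.
#' Every significant finding — an ellipsoid centre after recurrent-region
#' collapse for peak clustering, a supra-threshold local maximum for the
#' comparator — is classified as a hit when it lies within `hit_radius_mm`
#' of the seed centre of the source-location distribution, and a miss
#' otherwise. (Per-participant true locations differ within a group, so the
#' distribution centre is the reference; `hit_reference` switches to the
#' group's realized mean location.)
#'
#' @param cfg a [sim_config()]; its `moment_nAm` is overridden per
#'   magnitude.
#' @param magnitudes source magnitudes to sweep (nAm).
#' @param n_groups,group_size,pool_size protocol sizes (20 groups of 8 from
#'   a pool of 10).
#' @param m peaks per participant for the clustering method.
#' @param n_min smallest subgroup size tested; the default, `group_size`,
#'   asks whether all members' peaks cluster, giving at most one candidate
#'   region per group.
#' @param K clustering permutations per group.
#' @param alpha significance level for both methods.
#' @param snpm_perms sign-flip permutations for the comparator.
#' @param variance_smoothing_mm comparator variance smoothing FWHM.
#' @param methods which methods to run.
#' @param hit_radius_mm hit/miss distance criterion (20 mm).
#' @param hit_reference `"seed_centre"` (default) or `"group_mean"`.
#' @param seed optional integer seed; all randomness flows from it.
#' @return An object of class `hitmiss_experiment`: `counts` (data frame
#'   with magnitude, method, hits, misses), `findings` (per magnitude /
#'   method / group, mm centres and distances), and the settings.
#' @export
run_hit_miss_experiment <- function(cfg, magnitudes, n_groups = 20,
                                    group_size = 8, pool_size = 10, m = 5,
                                    n_min = group_size, K = 500,
                                    alpha = 0.05, snpm_perms = 256,
                                    variance_smoothing_mm = 25,
                                    methods = c("peakclust", "snpm"),
                                    hit_radius_mm = 20,
                                    hit_reference = c("seed_centre",
                                                      "group_mean"),
                                    seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  methods <- match.arg(methods, several.ok = TRUE)
  hit_reference <- match.arg(hit_reference)
  if (!is.null(seed)) set.seed(seed)
  grid <- beamformer_grid(cfg$sensors)
  counts <- list()
  findings <- list()

  for (mag in magnitudes) {
    cfg$moment_nAm <- mag
    pool <- simulate_group(cfg, pool_size)
    images <- lapply(pool$participants, beamform_image,
                     sensors = cfg$sensors, grid = grid,
                     noise_var = noise_sd_T(cfg)^2)
    peaklists <- mapply(function(img, id)
      find_local_maxima(img, sign = "positive", participant = id),
      images, names(images), SIMPLIFY = FALSE)
    true_locs <- t(vapply(pool$participants, `[[`, numeric(3),
                          "true_location_mm"))

    tallies <- sapply(methods, function(x) c(hits = 0L, misses = 0L),
                      simplify = FALSE)
    for (g in seq_len(n_groups)) {
      ids <- sample.int(pool_size, group_size)
      ref <- if (hit_reference == "seed_centre") cfg$seed_mni_mm
             else colMeans(true_locs[ids, , drop = FALSE])
      centres <- list()
      if ("peakclust" %in% methods) {
        scan <- peakclust(peaklists[ids], m_start = m, m_end = m,
                          n_min = n_min, perms = K, alpha = alpha)
        reg <- reported_regions(scan)
        centres$peakclust <- as.matrix(reg[, c("x", "y", "z"), drop = FALSE])
      }
      if ("snpm" %in% methods) {
        sn <- snpm_like_test(images[ids],
                             variance_smoothing_mm = variance_smoothing_mm,
                             alpha = alpha, n_perms = snpm_perms,
                             cache_key = "hitmiss_grid")
        centres$snpm <- sn$peaks_mm
      }
      for (meth in names(centres)) {
        ctr <- centres[[meth]]
        if (!nrow(ctr)) next
        dist <- sqrt(rowSums(sweep(ctr, 2, ref)^2))
        tallies[[meth]]["hits"] <- tallies[[meth]]["hits"] +
          sum(dist < hit_radius_mm)
        tallies[[meth]]["misses"] <- tallies[[meth]]["misses"] +
          sum(dist >= hit_radius_mm)
        findings[[length(findings) + 1L]] <- data.frame(
          magnitude_nAm = mag, method = meth, group = g,
          x = ctr[, 1], y = ctr[, 2], z = ctr[, 3], distance_mm = dist)
      }
    }
    for (meth in methods)
      counts[[length(counts) + 1L]] <- data.frame(
        magnitude_nAm = mag, method = meth,
        hits = unname(tallies[[meth]]["hits"]),
        misses = unname(tallies[[meth]]["misses"]))
  }
  structure(list(counts = do.call(rbind, counts),
                 findings = if (length(findings)) do.call(rbind, findings)
                            else NULL,
                 settings = list(n_groups = n_groups,
                                 group_size = group_size,
                                 pool_size = pool_size, m = m,
                                 n_min = n_min, K = K, alpha = alpha,
                                 snpm_perms = snpm_perms,
                                 variance_smoothing_mm = variance_smoothing_mm,
                                 hit_radius_mm = hit_radius_mm,
                                 hit_reference = hit_reference,
                                 seed = seed)),
            class = "hitmiss_experiment")
}

#' @export
print.hitmiss_experiment <- function(x, ...) {
  s <- x$settings
  cat(sprintf(
    "Hit/miss experiment: %d groups of %d from a pool of %d (M = %d)\n",
    s$n_groups, s$group_size, s$pool_size, s$m))
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Plot hit and miss counts against source magnitude
#'
#' @param x a [run_hit_miss_experiment()] result.
#' @param ... ignored.
#' @export
plot.hitmiss_experiment <- function(x, ...) {
  cts <- x$counts
  meths <- unique(cts$method)
  cols <- grDevices::hcl.colors(max(2L, length(meths)), "Dark 3")
  plot(range(cts$magnitude_nAm), c(0, max(cts$hits, cts$misses)),
       type = "n", xlab = "source magnitude (nAm)", ylab = "count",
       main = "Hits (solid) and misses (dashed)")
  for (i in seq_along(meths)) {
    sub <- cts[cts$method == meths[i], ]
    graphics::lines(sub$magnitude_nAm, sub$hits, col = cols[i], lty = 1,
                    type = "b", pch = 19)
    graphics::lines(sub$magnitude_nAm, sub$misses, col = cols[i], lty = 2,
                    type = "b", pch = 1)
  }
  graphics::legend("topleft", legend = meths, col = cols[seq_along(meths)],
                   lty = 1, bty = "n")
  invisible(x)
}
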