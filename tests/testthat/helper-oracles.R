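# Independent oracles used across the suite. Each deliberately avoids the
# code path it checks: the peak oracle scans every voxel's neighbours with
# explicit loops; the cluster oracle enumerates all one-peak-per-participant
# subsets; the field oracle is the free-space Biot-Savart law projected
# radially (volume currents of a spherical conductor are radially silent).

# exhaustive 18-neighbour local-maximum scan (positive sign)
oracle_local_maxima <- function(values, mask = NULL) {
  d <- dim(values)
  if (is.null(mask)) mask <- array(TRUE, d)
  mask <- mask & is.finite(values)
  out <- NULL
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!mask[i, j, k]) next
    v <- values[i, j, k]
    ismax <- TRUE
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      s2 <- di^2 + dj^2 + dk^2
      if (s2 < 1 || s2 > 2) next            # 18-connectivity
      ii <- i + di; jj <- j + dj; kk <- k + dk
      if (ii < 1 || jj < 1 || kk < 1 || ii > d[1] || jj > d[2] || kk > d[3])
        next                                 # outside volume: ignored
      if (!mask[ii, jj, kk]) next            # outside mask: ignored
      if (values[ii, jj, kk] >= v) { ismax <- FALSE; break }
    }
    if (ismax) out <- rbind(out, c(i, j, k))
  }
  out
}

# minimum major radius over every one-peak-per-participant subset using all
# participants (feasible for m^N small)
oracle_min_radius <- function(pls) {
  combos <- expand.grid(lapply(pls, function(pl) seq_along(pl$value)))
  ids <- vapply(pls, `[[`, character(1), "participant")
  best <- Inf
  for (i in seq_len(nrow(combos))) {
    loc <- t(mapply(function(pl, j) pl$loc_mm[j, ], pls,
                    unlist(combos[i, ])))
    e <- fit_ellipsoid(loc, ids)
    best <- min(best, e$major_radius_mm)
  }
  best
}

# radial component of the free-space field of a current dipole q (A m) at
# r0 (m), measured along each sensor's radial orientation
oracle_radial_field <- function(r0, q, sens) {
  mu0 <- 4e-7 * pi
  r <- sens$positions
  a <- sweep(r, 2, r0)
  an <- sqrt(rowSums(a^2))
  qxa <- cbind(q[2] * a[, 3] - q[3] * a[, 2],
               q[3] * a[, 1] - q[1] * a[, 3],
               q[1] * a[, 2] - q[2] * a[, 1])
  rowSums(mu0 / (4 * pi) * qxa / an^3 * sens$orientations)
}

# random peak lists for engine tests
random_peaklists <- function(n_participants, n_peaks, range_mm = 50) {
  lapply(seq_len(n_participants), function(i)
    peak_list(sprintf("p%d", i),
              matrix(runif(3 * n_peaks, -range_mm, range_mm), n_peaks, 3),
              runif(n_peaks)))
}

# shift every peak location by a fixed mm vector
shift_peaklists <- function(pls, t_mm) {
  lapply(pls, function(pl) {
    pl$loc_mm <- sweep(pl$loc_mm, 2, -t_mm)
    pl
  })
}
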