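#' Peak-clustering group analysis
#'
#' The package's main entry point. For each peak count M in
#' `m_start:m_end`, the top-M peaks of every participant are pooled, the
#' smallest one-peak-per-participant confidence ellipsoid is found for every
#' subgroup size N' in `n_min:N` ([smallest_clusters()]), and its major 95%
#' radius is compared against a rank-shuffling permutation null
#' ([build_null()]) constructed with identical search settings. P-values use
#' the add-one permutation estimator; significance is declared at the
#' log2-doubling Bonferroni threshold [corrected_alpha()] for the scanned M
#' range, so the family-wise error over the whole scan is `alpha`.
#'
#' @param peaklists list of full [peak_list()] objects, one per participant
#'   (e.g. from [find_local_maxima()] or [read_peak_table()]).
#' @param m_start,m_end range of peak counts scanned. Equal values test a
#'   single M with no correction.
#' @param n_min smallest subgroup size reported.
#' @param perms permutations per M (paper-conventional default 500).
#' @param alpha family-wise error rate.
#' @param iterations,restarts cluster-search settings, shared by the
#'   observed and null searches.
#' @param seed optional integer seed; all randomness (null permutations and
#'   k-means seeding) flows from it.
#' @return An object of class `peakclust` with components `table` (one row
#'   per (M, N') cluster found: centre, volume, major radius, mean member
#'   value, raw p, significance flag), `ellipsoids` (matching list),
#'   `null_crit` (per (M, N'), the radius exceeded by 95% of chance
#'   clusters), `threshold` (corrected test-wise level), and the settings.
#' @seealso [reported_regions()], [heuristic_curve()], [report()]
#' @export
peakclust <- function(peaklists, m_start = 2, m_end = 40, n_min = 5,
                      perms = 500, alpha = 0.05, iterations = 30,
                      restarts = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(peaklists) >= 2)
  n_part <- length(peaklists)
  m_values <- seq.int(m_start, m_end)
  n_values <- seq.int(n_min, n_part)
  threshold <- corrected_alpha(alpha, m_start, m_end)

  rows <- list()
  ells <- list()
  # significance radius: small radii are the extreme tail, so the radius a
  # cluster must beat at 0.05 is the 5th percentile of the null radii
  rcrit <- matrix(NA_real_, length(m_values), length(n_values),
                  dimnames = list(m_values, n_values))
  for (mi in seq_along(m_values)) {
    m <- m_values[mi]
    obs <- smallest_clusters(peaklists, m = m, n_min = n_min,
                             iterations = iterations, restarts = restarts)
    null <- build_null(peaklists, m = m, n_min = n_min, K = perms,
                       iterations = iterations, restarts = restarts)
    rcrit[mi, ] <- apply(null$radii, 2, function(r)
      if (all(is.na(r))) NA_real_ else quantile(r, 0.05, na.rm = TRUE))
    for (key in names(obs$ellipsoids)) {
      ell <- obs$ellipsoids[[key]]
      if (is.null(ell)) next
      p <- p_value(ell, null)
      rows[[length(rows) + 1L]] <- data.frame(
        M = m, N = as.integer(key),
        x = ell$center_mm[1], y = ell$center_mm[2], z = ell$center_mm[3],
        volume_mm3 = ell$volume_mm3,
        major_radius_mm = ell$major_radius_mm,
        mean_value = ell$mean_value,
        p = p, significant = p < threshold)
      ells[[length(ells) + 1L]] <- ell
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(M = integer(0), N = integer(0), x = numeric(0),
               y = numeric(0), z = numeric(0), volume_mm3 = numeric(0),
               major_radius_mm = numeric(0), mean_value = numeric(0),
               p = numeric(0), significant = logical(0))
  rownames(tab) <- NULL
  structure(list(table = tab, ellipsoids = ells, null_crit = rcrit,
                 m_values = m_values, n_values = n_values,
                 alpha = alpha, threshold = threshold, perms = perms,
                 n_participants = n_part, n_min = n_min,
                 iterations = iterations, restarts = restarts, seed = seed,
                 call = match.call()),
            class = "peakclust")
}

#' Collapse recurrent regions of a scan for reporting
#'
#' The same anatomical region typically yields significant ellipsoids across
#' a range of M (and several subgroup sizes). Two significant clusters are
#' treated as the same region when they share at least one member peak (same
#' participant, same location); within each region the cluster with the
#' largest N', breaking ties by smallest major radius, is reported.
#'
#' @param scan a [peakclust()] result.
#' @param significant_only collapse only the significant rows (default).
#' @return A data frame in the layout of `scan$table`, one row per region,
#'   with a `region` index column.
#' @export
reported_regions <- function(scan, significant_only = TRUE) {
  stopifnot(inherits(scan, "peakclust"))
  tab <- scan$table
  keep <- if (significant_only) which(tab$significant) else seq_len(nrow(tab))
  if (!length(keep)) return(cbind(tab[0, ], region = integer(0)))
  mem_keys <- lapply(scan$ellipsoids[keep], function(e)
    paste(e$members$participant,
          round(e$members$x, 6), round(e$members$y, 6),
          round(e$members$z, 6)))
  # union-find over shared member peaks
  parent <- seq_along(keep)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_along(keep)) for (j in seq_len(i - 1L)) {
    if (length(intersect(mem_keys[[i]], mem_keys[[j]]))) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  comp <- vapply(seq_along(keep), find, integer(1))
  out <- lapply(split(seq_along(keep), comp), function(ix) {
    sub <- tab[keep[ix], , drop = FALSE]
    sub <- sub[order(-sub$N, sub$major_radius_mm), , drop = FALSE]
    sub[1, , drop = FALSE]
  })
  out <- do.call(rbind, out)
  out$region <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' @export
print.peakclust <- function(x, ...) {
  cat(sprintf(
    "Peak-clustering scan: N = %d participants, M = %d..%d, %d permutations\n",
    x$n_participants, min(x$m_values), max(x$m_values), x$perms))
  cat(sprintf("Corrected test-wise threshold: %.4f (family alpha %.2f)\n",
              x$threshold, x$alpha))
  reg <- reported_regions(x)
  if (nrow(reg) == 0L) {
    cat("No significant clusters.\n")
  } else {
    cat(sprintf("%d significant region(s):\n", nrow(reg)))
    print(data.frame(N = reg$N, M = reg$M,
                     x = round(reg$x, 1), y = round(reg$y, 1),
                     z = round(reg$z, 1),
                     volume_mm3 = round(reg$volume_mm3),
                     major_radius_mm = round(reg$major_radius_mm, 1),
                     mean_value = round(reg$mean_value, 2),
                     p = round(reg$p, 3)),
          row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.peakclust <- function(object, ...) {
  structure(list(scan = object,
                 regions = reported_regions(object),
                 J = heuristic_J(heuristic_curve(object))),
            class = "summary.peakclust")
}

#' @export
print.summary.peakclust <- function(x, ...) {
  print(x$scan)
  cat("\nAll clusters:\n")
  tab <- x$scan$table
  tab[c("x", "y", "z", "major_radius_mm")] <-
    lapply(tab[c("x", "y", "z", "major_radius_mm")], round, digits = 1)
  tab$volume_mm3 <- round(tab$volume_mm3)
  tab$mean_value <- round(tab$mean_value, 2)
  tab$p <- round(tab$p, 3)
  print(tab, row.names = FALSE)
  ok <- !is.na(x$J$m_opt)
  if (any(ok)) {
    cat("\nHeuristic optimal M per subgroup size:\n")
    print(data.frame(N = x$scan$n_values[ok], m_opt = x$J$m_opt[ok]),
          row.names = FALSE)
  }
  invisible(x)
}

#' Plot a peak-clustering scan
#'
#' Left panel: the null 95% confidence radius R against the number of peaks
#' M, one curve per subgroup size. Right panel: the trade-off heuristic
#' J(M, N') with its per-subgroup minima marked; crosses mark (M, N') cells
#' with at least one significant cluster.
#'
#' @param x a [peakclust()] result.
#' @param ... ignored.
#' @export
plot.peakclust <- function(x, ...) {
  crv <- heuristic_curve(x)
  J <- heuristic_J(crv)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  cols <- grDevices::hcl.colors(length(crv$n), "Dark 3")
  graphics::matplot(crv$m, crv$R, type = "l", lty = 1, col = cols,
                    xlab = "number of peaks M",
                    ylab = "null 95% radius R (mm)",
                    main = "Chance cluster size")
  graphics::legend("topright", legend = paste0("N'=", crv$n), col = cols,
                   lty = 1, cex = 0.8, bty = "n")
  graphics::matplot(J$m, J$J, type = "l", lty = 1, col = cols,
                    xlab = "number of peaks M", ylab = "J",
                    main = "Rank vs consistency trade-off")
  sig <- x$table[x$table$significant, , drop = FALSE]
  if (nrow(sig)) {
    ni <- match(sig$N, x$n_values)
    mi <- match(sig$M, x$m_values)
    graphics::points(sig$M, J$J[cbind(mi, ni)], pch = 4, col = cols[ni])
  }
  for (i in seq_along(crv$n)) {
    if (!is.na(J$m_opt[i])) {
      mi <- match(J$m_opt[i], J$m)
      graphics::points(J$m_opt[i], J$J[mi, i], pch = 19, col = cols[i])
    }
  }
  invisible(x)
}
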