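#' Smallest one-peak-per-participant clusters
#'
#' Pools the top-M peaks of all participants (N x M points) and searches for
#' the smallest confidence ellipsoid containing at most one peak per
#' participant, for every achieved subgroup size from `n_min` up to N. The
#' search runs k-means with k = M clusters: after each assignment every
#' cluster is trimmed so no participant contributes more than one point
#' (keeping the point nearest the cluster centroid; ties keep the
#' better-ranked peak), centroids are recomputed from the trimmed members,
#' and the procedure repeats for `iterations` rounds. Across all rounds and
#' `restarts` independent k-means++ seedings, the trimmed cluster with the
#' smallest major 95% radius is recorded for each participant count. Trimmed
#' clusters of fewer than 2 points are discarded. Cluster size is always
#' compared by major radius; volume is reported but never used to rank.
#'
#' @param peaklists list of [peak_list()] objects, one per participant.
#' @param m number of top-ranked peaks taken from each participant (lists
#'   longer than `m` are truncated with [top_m()]).
#' @param n_min smallest subgroup size of interest (>= 2).
#' @param iterations k-means rounds per restart.
#' @param restarts independent k-means++ seedings; the recorded radii are
#'   non-increasing in the number of restarts.
#' @param seed optional integer seed for the search RNG.
#' @return An object of class `cluster_set`: a list with `ellipsoids` (one
#'   [fit_ellipsoid()] result per achieved subgroup size, named by N'),
#'   `radii` (named numeric, NA where no cluster of that size was found),
#'   and the search settings.
#' @export
smallest_clusters <- function(peaklists, m, n_min, iterations = 30,
                              restarts = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(peaklists) >= 2, m >= 1, n_min >= 2)
  n_part <- length(peaklists)
  if (n_part < n_min)
    stop("n_min exceeds the number of participants")
  if (m * n_part < n_min)
    stop("fewer pooled peaks (m * N) than n_min")
  pls <- lapply(peaklists, top_m, m = m)
  pooled <- pool_peaks(pls)
  res <- cpp_smallest_clusters(pooled$loc, pooled$pid, pooled$rank,
                               as.integer(m), as.integer(n_min),
                               as.integer(iterations), as.integer(restarts))
  sizes <- n_min:n_part
  ells <- vector("list", length(sizes))
  names(ells) <- as.character(sizes)
  for (i in seq_along(sizes)) {
    idx <- res$members[[i]]
    if (!is.null(idx))
      ells[[i]] <- fit_ellipsoid(pooled$loc[idx, , drop = FALSE],
                                 pooled$participant[idx],
                                 pooled$value[idx])
  }
  radii <- as.numeric(res$radii)
  names(radii) <- names(ells)
  structure(list(ellipsoids = ells, radii = radii, m = m, n_min = n_min,
                 n_participants = n_part, iterations = iterations,
                 restarts = restarts),
            class = "cluster_set")
}

# flatten a list of peak lists into pooled point arrays
pool_peaks <- function(pls) {
  loc <- do.call(rbind, lapply(pls, `[[`, "loc_mm"))
  npk <- vapply(pls, function(p) length(p$value), integer(1))
  list(loc = loc,
       pid = rep(seq_along(pls), npk),
       rank = unlist(lapply(pls, `[[`, "rank"), use.names = FALSE),
       value = unlist(lapply(pls, `[[`, "value"), use.names = FALSE),
       participant = rep(vapply(pls, `[[`, character(1), "participant"), npk))
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("Cluster set: M = %d, N = %d, subgroups %d..%d\n",
              x$m, x$n_participants, x$n_min, x$n_participants))
  df <- data.frame(N = as.integer(names(x$radii)),
                   major_radius_mm = round(x$radii, 2))
  print(df, row.names = FALSE)
  invisible(x)
}
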