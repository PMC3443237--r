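# two-sided Gaussian 95% half-width multiplier applied to per-axis SDs;
# applied identically to observed and null radii, so p-values do not depend
# on this constant
z95 <- qnorm(0.975)

#' Fit a confidence ellipsoid to member peaks
#'
#' The ellipsoid centre is the centroid of the member locations; axes are the
#' eigenvectors of the 3x3 coordinate covariance (sample covariance, n-1
#' denominator) and the per-axis 95% radii are `1.959964 * sqrt(eigenvalue)`,
#' the two-sided Gaussian 95% half-width of the spread along each axis. The
#' cluster-size statistic used throughout the package is the major (largest)
#' radius. Degenerate directions (fewer than 3 distinct points) get radius 0.
#'
#' @param loc_mm numeric matrix (members x 3) of mm coordinates.
#' @param participants character vector of member participant ids; at most
#'   one peak per participant is allowed.
#' @param value optional statistic values of the member peaks (used for the
#'   reported mean value).
#' @return An object of class `ellipsoid` with fields `center_mm`, `axes`
#'   (columns are unit direction vectors), `radii_mm` (descending),
#'   `major_radius_mm`, `volume_mm3`, `members` (data frame),
#'   `n_participants`, `mean_value`.
#' @export
fit_ellipsoid <- function(loc_mm, participants, value = NULL) {
  loc_mm <- matrix(as.numeric(loc_mm), ncol = 3L)
  n <- nrow(loc_mm)
  if (n < 2L) stop("need at least 2 points to fit an ellipsoid")
  participants <- as.character(participants)
  if (anyDuplicated(participants))
    stop("at most one peak per participant")
  ctr <- colMeans(loc_mm)
  S <- cov(loc_mm)
  e <- eigen(S, symmetric = TRUE)        # eigenvalues descending
  ev <- pmax(e$values, 0)
  ev[ev < max(ev) * 1e-12] <- 0          # degenerate directions: radius 0
  radii <- z95 * sqrt(ev)
  members <- data.frame(participant = participants,
                        x = loc_mm[, 1], y = loc_mm[, 2], z = loc_mm[, 3])
  if (!is.null(value)) members$value <- as.numeric(value)
  structure(list(center_mm = ctr,
                 axes = e$vectors,
                 radii_mm = radii,
                 major_radius_mm = radii[1],
                 volume_mm3 = 4 / 3 * pi * prod(radii),
                 members = members,
                 n_participants = n,
                 mean_value = if (is.null(value)) NA_real_
                              else mean(as.numeric(value))),
            class = "ellipsoid")
}

#' @export
print.ellipsoid <- function(x, ...) {
  cat(sprintf(
    "Confidence ellipsoid: N = %d, centre (%.1f, %.1f, %.1f) mm\n",
    x$n_participants, x$center_mm[1], x$center_mm[2], x$center_mm[3]))
  cat(sprintf("  95%% radii (mm): %.2f, %.2f, %.2f; volume %.0f mm^3\n",
              x$radii_mm[1], x$radii_mm[2], x$radii_mm[3], x$volume_mm3))
  if (!is.na(x$mean_value))
    cat(sprintf("  mean member value: %.3f\n", x$mean_value))
  invisible(x)
}
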