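# session cache for leadfield matrices / smoothing kernels (pure functions
# of the geometry, expensive enough to reuse)
.pkcache <- new.env(parent = emptyenv())

#' Source-space grid inside the conducting sphere
#'
#' Regular mm grid covering the sphere interior; the analysis mask keeps
#' voxels at least `interior_margin_mm` inside the sphere surface (the
#' lead field, and hence the beamformer, degenerates towards the surface
#' and at the centre).
#'
#' @param sensors a [meg_sensor_array()].
#' @param spacing_mm grid step (default 10 mm).
#' @param interior_margin_mm minimum depth below the sphere surface.
#' @return An object of class `bf_grid`: `loc_mm` (V x 3 mm coordinates of
#'   in-mask voxels), `dim`, `affine`, `mask` (logical array), `index`
#'   (linear indices of in-mask voxels).
#' @export
beamformer_grid <- function(sensors, spacing_mm = 10,
                            interior_margin_mm = 10) {
  rad <- sensors$sphere_radius_m * 1000
  off <- seq(-(rad - interior_margin_mm), rad - interior_margin_mm,
             by = spacing_mm)
  ctr <- sensors$sphere_center_mni_mm
  gx <- off + ctr[1]; gy <- off + ctr[2]; gz <- off + ctr[3]
  dims <- c(length(gx), length(gy), length(gz))
  coords <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  d2 <- rowSums(sweep(coords, 2, ctr)^2)
  inside <- d2 <= (rad - interior_margin_mm)^2
  mask <- array(inside, dims)
  affine <- rbind(cbind(diag(spacing_mm, 3), c(gx[1], gy[1], gz[1])),
                  c(0, 0, 0, 1))
  structure(list(loc_mm = coords[inside, , drop = FALSE], dim = dims,
                 affine = affine, mask = mask, index = which(inside),
                 spacing_mm = spacing_mm),
            class = "bf_grid")
}

# S x 2V leadfield matrix over the grid, cached per geometry
grid_leadfields <- function(grid, sensors) {
  key <- paste0("L|", sensors$n_channels, "|", sensors$array_radius_m, "|",
                sensors$sphere_radius_m, "|",
                paste(sensors$sphere_center_mni_mm, collapse = ","), "|",
                grid$spacing_mm, "|", nrow(grid$loc_mm))
  if (!is.null(.pkcache[[key]])) return(.pkcache[[key]])
  V <- nrow(grid$loc_mm)
  L <- matrix(0, sensors$n_channels, 2 * V)
  ctr <- sensors$sphere_center_mni_mm
  for (v in seq_len(V)) {
    # a voxel at the sphere centre has no tangential basis and no external
    # field; leave its gain at zero so it is marked invalid downstream
    if (sqrt(sum((grid$loc_mm[v, ] - ctr)^2)) < 1e-3) next
    L[, c(2 * v - 1, 2 * v)] <- sphere_leadfield(grid$loc_mm[v, ], sensors)
  }
  .pkcache[[key]] <- L
  L
}

# Moore-Penrose pseudo-inverse, relative tolerance on singular values
pinv <- function(M, tol = 1e-12) {
  s <- svd(M)
  keep <- s$d > tol * s$d[1]
  if (!any(keep)) return(matrix(0, ncol(M), nrow(M)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' LCMV weights and optimal orientation for one location
#'
#' Linearly constrained minimum-variance spatial filter: output power is
#' minimised over the covariance window subject to unit gain at the target.
#' The scalar orientation is the one maximising output SNR — the
#' generalized eigenvector of the pair `(H' C^-1 H, H' C^-2 H)` at the
#' largest eigenvalue — and the weights are `W = C^-1 H eta`, scaled so
#' that `W' H eta = 1`.
#'
#' @param H S x 2 tangential lead field (e.g. [sphere_leadfield()]); when it
#'   carries a `"basis"` attribute the 3-D orientation is returned too.
#' @param C S x S measurement covariance over the covariance window; no
#'   regularization is applied by default (see `mu`).
#' @param mu Tikhonov regularization as a fraction of the mean sensor
#'   power: the covariance used is `C + mu * mean(diag(C)) * I`. Default 0
#'   (maximum spatial resolution, noisier images).
#' @return List with `weights` (S), `eta` (unit 2-vector in the tangential
#'   basis), `orientation` (unit 3-vector or NULL), and `valid` (FALSE when
#'   the location's lead field makes `H' C^-1 H` effectively singular, e.g.
#'   at the sphere centre).
#' @export
lcmv_weights <- function(H, C, mu = 0) {
  if (mu > 0) C <- C + mu * mean(diag(C)) * diag(nrow(C))
  Cinv <- pinv(C)
  CiH <- Cinv %*% H
  A <- crossprod(H, CiH)       # H' C^-1 H
  B <- crossprod(CiH)          # H' C^-2 H
  if (!all(is.finite(A)) || !all(is.finite(B)) ||
      det(B) <= 0 || det(A) <= .Machine$double.eps * mean(diag(A))^2)
    return(list(weights = NULL, eta = NULL, orientation = NULL,
                valid = FALSE))
  ev <- eigen(solve(B, A))
  i <- which.max(Re(ev$values))
  eta <- Re(ev$vectors[, i])
  eta <- eta / sqrt(sum(eta^2))
  gain <- as.numeric(t(eta) %*% A %*% eta)
  W <- as.numeric(CiH %*% eta) / gain
  basis <- attr(H, "basis")
  ori <- if (is.null(basis)) NULL else {
    o <- as.numeric(basis %*% eta)
    o / sqrt(sum(o^2))
  }
  list(weights = W, eta = eta, orientation = ori, valid = TRUE)
}

# per-voxel 2x2 quadratic-form entries: M_v = t(P[,2v-1:2v]) %*% Q[,2v-1:2v]
blocks2 <- function(P, Q, o, e) {
  list(m11 = colSums(P[, o] * Q[, o]),
       m12 = colSums(P[, o] * Q[, e]),
       m22 = colSums(P[, e] * Q[, e]))
}

qform2 <- function(M, e1, e2) e1^2 * M$m11 + 2 * e1 * e2 * M$m12 + e2^2 * M$m22

#' Volumetric pseudo-t beamformer image
#'
#' Runs the LCMV scalar beamformer at every grid voxel of an epoched
#' recording and returns the normalized active-minus-control power
#' difference (pseudo-t) image: per voxel,
#' `T = (W' C_active W - W' C_control W) / (sigma2 W' W)`, where the
#' weights come from a single covariance window spanning both states and
#' `sigma2` is the sensor noise-floor variance (identity noise model). The
#' rank ordering of image peaks — all the clustering consumes — is
#' invariant to the constant in the denominator.
#'
#' @param epochs a `meg_epochs` recording ([simulate_participant()]).
#' @param sensors the [meg_sensor_array()] that produced it.
#' @param grid a [beamformer_grid()]; defaults to a 10 mm grid.
#' @param noise_var sensor noise variance sigma2 (Tesla^2). Default: the
#'   mean diagonal of the control-state covariance, which in a simulation
#'   whose passive epochs are pure noise estimates the true noise floor;
#'   pass the known value when exact calibration matters.
#' @param mu Tikhonov regularization fraction (see [lcmv_weights()]);
#'   default 0, matching an unregularized maximum-resolution analysis.
#' @return A [volumetric_image()] of pseudo-t values; voxels with a
#'   degenerate lead field are masked out.
#' @export
beamform_image <- function(epochs, sensors, grid = NULL, noise_var = NULL,
                           mu = 0) {
  stopifnot(inherits(epochs, "meg_epochs"))
  if (is.null(grid)) grid <- beamformer_grid(sensors)
  dat <- epochs$data                      # epochs x S x samples
  ne <- dim(dat)[1]; S <- dim(dat)[2]; ns <- dim(dat)[3]
  # samples as rows: (epochs * samples) x channels
  X <- matrix(aperm(dat, c(3, 1, 2)), ne * ns, S)
  ep_of_row <- rep(seq_len(ne), each = ns)
  act <- epochs$labels[ep_of_row] == "active"
  C <- cov(X)
  Ca <- cov(X[act, , drop = FALSE])
  Cc <- cov(X[!act, , drop = FALSE])
  if (is.null(noise_var)) noise_var <- mean(diag(Cc))
  if (mu > 0) C <- C + mu * mean(diag(C)) * diag(S)

  L <- grid_leadfields(grid, sensors)
  Cinv <- pinv(C)
  CiL <- Cinv %*% L
  V <- nrow(grid$loc_mm)
  o <- 2 * seq_len(V) - 1L
  e <- o + 1L

  A <- blocks2(L, CiL, o, e)              # H' C^-1 H
  B <- blocks2(CiL, CiL, o, e)            # H' C^-2 H
  # generalized eigenproblem A eta = lambda B eta, closed form per voxel
  qa <- B$m11 * B$m22 - B$m12^2
  qb <- -(A$m11 * B$m22 + A$m22 * B$m11 - 2 * A$m12 * B$m12)
  qc <- A$m11 * A$m22 - A$m12^2
  disc <- pmax(qb^2 - 4 * qa * qc, 0)
  lam <- (-qb + sqrt(disc)) / (2 * qa)
  v0 <- A$m11 - lam * B$m11
  v1 <- A$m12 - lam * B$m12
  w1 <- A$m22 - lam * B$m22
  use1 <- (v0^2 + v1^2) >= (w1^2 + v1^2)
  e1 <- ifelse(use1, -v1, w1)
  e2 <- ifelse(use1, v0, -v1)
  nrm <- sqrt(e1^2 + e2^2)
  deg <- !is.finite(nrm) | nrm < .Machine$double.eps
  e1 <- ifelse(deg, 1, e1 / nrm)
  e2 <- ifelse(deg, 0, e2 / nrm)

  Ma <- blocks2(CiL, Ca %*% CiL, o, e)
  Mc <- blocks2(CiL, Cc %*% CiL, o, e)
  tval <- (qform2(Ma, e1, e2) - qform2(Mc, e1, e2)) /
    (noise_var * qform2(B, e1, e2))
  tval[!is.finite(lam) | qa <= 0] <- NA_real_

  vals <- array(NA_real_, grid$dim)
  vals[grid$index] <- tval
  volumetric_image(vals, grid$affine, mask = grid$mask)
}
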