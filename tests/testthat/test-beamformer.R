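test_that("identity covariance gives weights in the leadfield span", {
  set.seed(81)
  H <- qr.Q(qr(matrix(rnorm(20), 10, 2)))   # orthonormal columns
  w <- lcmv_weights(H, diag(10))
  expect_true(w$valid)
  # W = H eta up to the unit-gain scaling: residual out of span is zero
  resid <- w$weights - H %*% crossprod(H, w$weights)
  expect_equal(max(abs(resid)), 0, tolerance = 1e-12)
  expect_equal(as.numeric(crossprod(w$weights, H %*% w$eta)), 1,
               tolerance = 1e-12)
})

test_that("unit gain holds at every valid voxel of a realistic covariance", {
  sens <- meg_sensor_array()
  cfg <- sim_config(moment_nAm = 30)
  set.seed(82)
  p <- simulate_participant(cfg)
  X <- matrix(aperm(p$data, c(3, 1, 2)), 60 * 40, 275)
  C <- cov(X)
  for (i in 1:10) {
    loc <- sens$sphere_center_mni_mm + runif(3, -50, 50)
    H <- sphere_leadfield(loc, sens)
    w <- lcmv_weights(H, C)
    expect_true(w$valid)
    expect_lt(abs(sum(w$weights * (H %*% w$eta)) - 1), 1e-10)
    expect_equal(sum(w$orientation^2), 1, tolerance = 1e-12)
  }
})

test_that("weights are equivariant under channel permutation", {
  sens <- meg_sensor_array(n_channels = 40)
  set.seed(83)
  H <- sphere_leadfield(c(30, -20, 25), sens)
  X <- matrix(rnorm(400 * 40, sd = 1e-13), 400, 40)
  C <- cov(X)
  perm <- sample(40)
  a <- lcmv_weights(H, C)
  b <- lcmv_weights(H[perm, ], C[perm, perm])
  expect_equal(b$weights, a$weights[perm], tolerance = 1e-8)
})

test_that("equal active and control covariances give a zero image", {
  # a recording whose labels are shuffled so both states share the data:
  # build one with no source and identical state covariances by symmetry
  cfg <- sim_config(moment_nAm = 0, n_epochs = 4, n_active = 2)
  set.seed(84)
  p <- simulate_participant(cfg)
  # force control data identical to active data
  p$data[p$labels == "passive", , ] <- p$data[p$labels == "active", , ]
  img <- beamform_image(p, cfg$sensors, noise_var = 8e-27)
  expect_equal(max(abs(img$values), na.rm = TRUE), 0, tolerance = 1e-8)
})

test_that("a pure-noise image has no systematic sign", {
  cfg <- sim_config(moment_nAm = 0)
  set.seed(85)
  p <- simulate_participant(cfg)
  img <- beamform_image(p, cfg$sensors, noise_var = 8e-27)
  v <- img$values[is.finite(img$values)]
  expect_lt(abs(mean(v)), 3 * sd(v) / sqrt(length(v)) + 0.01)
})

test_that("a strong source is localised within one grid step", {
  cfg <- sim_config(moment_nAm = 50)
  set.seed(86)
  p <- simulate_participant(cfg)
  img <- beamform_image(p, cfg$sensors, noise_var = 8e-27)
  pk <- find_local_maxima(img, "positive", p$participant)
  d <- sqrt(sum((pk$loc_mm[1, ] - p$true_location_mm)^2))
  expect_lt(d, 10 * sqrt(3) + 1e-9)   # one 10 mm grid step in 3-D
  # pseudo-t at the maximum clearly exceeds the off-source background
  expect_gt(pk$value[1], 10 * sd(img$values[is.finite(img$values)]))
})
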