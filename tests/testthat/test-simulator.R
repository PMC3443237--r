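test_that("sphere leadfield matches the radial Biot-Savart oracle", {
  sens <- meg_sensor_array()
  set.seed(71)
  for (rep in 1:4) {
    loc <- sens$sphere_center_mni_mm + runif(3, -40, 40)
    L <- sphere_leadfield(loc, sens)
    basis <- attr(L, "basis")
    r0 <- (loc - sens$sphere_center_mni_mm) / 1000
    for (j in 1:2) {
      orc <- oracle_radial_field(r0, 1e-9 * basis[, j], sens)
      expect_lt(max(abs(L[, j] - orc)) / max(abs(orc)), 1e-10)
    }
    # tangential basis is orthonormal and orthogonal to the radial direction
    expect_equal(crossprod(basis), diag(2), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(as.numeric(t(basis) %*% r0), c(0, 0), tolerance = 1e-12)
  }
})

test_that("central and radial dipoles are externally silent", {
  sens <- meg_sensor_array()
  expect_equal(sarvas_field(c(0, 0, 0), c(1e-9, 0, 0), sens),
               numeric(sens$n_channels))
  r0 <- c(0.03, -0.01, 0.02)
  rad <- 1e-9 * r0 / sqrt(sum(r0^2))
  expect_equal(max(abs(sarvas_field(r0, rad, sens))), 0, tolerance = 1e-25)
  # a tangential dipole at the same spot is not silent
  tang <- 1e-9 * c(-r0[2], r0[1], 0) / sqrt(r0[1]^2 + r0[2]^2)
  expect_gt(max(abs(sarvas_field(r0, tang, sens))), 1e-15)
})

test_that("field magnitude is linear in the dipole moment", {
  sens <- meg_sensor_array()
  r0 <- c(0.04, 0.01, -0.02)
  q <- c(0, 1e-9, 0)
  expect_equal(sarvas_field(r0, 5 * q, sens), 5 * sarvas_field(r0, q, sens))
})

test_that("locations outside the sphere or at its centre are rejected", {
  sens <- meg_sensor_array()
  expect_error(sphere_leadfield(sens$sphere_center_mni_mm + c(95, 0, 0),
                                sens), "outside")
  expect_error(sphere_leadfield(sens$sphere_center_mni_mm, sens), "centre")
})

test_that("simulated noise has the configured per-sample SD", {
  # 10 fT/sqrt(Hz) over 80 Hz -> 10 * sqrt(80) = 89.4 fT per sample
  cfg <- sim_config(moment_nAm = 0)
  set.seed(72)
  p <- simulate_participant(cfg)
  expect_equal(sd(p$data) * 1e15, 10 * sqrt(80), tolerance = 0.01)
  expect_equal(dim(p$data), c(60L, 275L, 40L))
  expect_equal(sum(p$labels == "active"), 30L)
})

test_that("passive epochs carry exactly no source contribution", {
  cfg0 <- sim_config(moment_nAm = 0)
  cfg1 <- sim_config(moment_nAm = 50)
  set.seed(73); p0 <- simulate_participant(cfg0)
  set.seed(73); p1 <- simulate_participant(cfg1)
  passive <- which(p1$labels == "passive")
  expect_identical(p1$data[passive, , ], p0$data[passive, , ])
  active <- which(p1$labels == "active")
  expect_false(identical(p1$data[active, , ], p0$data[active, , ]))
  # and a fixed RNG state reproduces the dataset bit for bit
  set.seed(73); p2 <- simulate_participant(cfg1)
  expect_identical(p1$data, p2$data)
  expect_identical(p1$true_location_mm, p2$true_location_mm)
})

test_that("source locations recover the configured centre and jitter", {
  cfg <- sim_config(moment_nAm = 0, n_epochs = 2, n_active = 1)
  set.seed(74)
  locs <- t(replicate(400, simulate_participant(cfg)$true_location_mm))
  expect_equal(unname(colMeans(locs)), c(52, -29, 13), tolerance = 1)
  expect_equal(unname(apply(locs, 2, sd)), rep(5, 3), tolerance = 0.6)
})

test_that("dipole orientations are unit-norm and tangential", {
  cfg <- sim_config(moment_nAm = 0, n_epochs = 2, n_active = 1)
  set.seed(75)
  for (i in 1:5) {
    p <- simulate_participant(cfg)
    u <- (p$true_location_mm - cfg$sensors$sphere_center_mni_mm)
    u <- u / sqrt(sum(u^2))
    expect_equal(sum(p$orientation^2), 1, tolerance = 1e-12)
    expect_equal(sum(p$orientation * u), 0, tolerance = 1e-12)
  }
})

test_that("YAML configs override defaults and reject unknown fields", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("moment_nAm: 35", "jitter_sd_mm: 2.5",
               "sensors:", "  n_channels: 50"), path)
  cfg <- read_sim_config(path)
  expect_equal(cfg$moment_nAm, 35)
  expect_equal(cfg$jitter_sd_mm, 2.5)
  expect_equal(cfg$sensors$n_channels, 50L)
  expect_equal(cfg$freq_hz, 40)
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("wavelength: 3", bad)
  expect_error(read_sim_config(bad), "unknown")
})
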