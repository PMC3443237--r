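test_that("a unique strict maximum is found at its mm coordinate", {
  v <- array(0, c(3, 3, 3))
  v[2, 2, 2] <- 5
  aff <- rbind(cbind(diag(2, 3), c(-10, 0, 30)), c(0, 0, 0, 1))
  pl <- find_local_maxima(volumetric_image(v, aff), "positive")
  expect_equal(length(pl$value), 1L)
  # voxel (2,2,2) is 0-based (1,1,1): affine maps it to origin + spacing
  expect_equal(unname(pl$loc_mm[1, ]), c(-10 + 2, 0 + 2, 30 + 2))
  expect_equal(pl$value, 5)
  expect_equal(pl$rank, 1L)
})

test_that("peak extraction matches the exhaustive 18-neighbour oracle", {
  aff <- rbind(cbind(diag(3), c(0, 0, 0)), c(0, 0, 0, 1))
  set.seed(101)
  for (rep in 1:5) {
    v <- array(rnorm(8^3), c(8, 8, 8))
    mask <- if (rep %% 2 == 0) array(runif(8^3) > 0.2, c(8, 8, 8)) else NULL
    pl <- find_local_maxima(volumetric_image(v, aff, mask), "positive")
    orc <- oracle_local_maxima(v, mask)
    got <- pl$loc_mm[order(pl$loc_mm[, 1], pl$loc_mm[, 2], pl$loc_mm[, 3]), ,
                     drop = FALSE]
    exp <- (orc - 1)[order(orc[, 1] - 1, orc[, 2] - 1, orc[, 3] - 1), ,
                     drop = FALSE]
    expect_equal(unname(got), unname(exp))
    # ranks are by descending value
    expect_true(all(diff(pl$value) <= 0))
  }
})

test_that("two maxima separated by one non-maximal voxel are both reported", {
  v <- array(0, c(5, 3, 3))
  v[2, 2, 2] <- 5
  v[3, 2, 2] <- 1
  v[4, 2, 2] <- 5
  aff <- diag(4)
  pl <- find_local_maxima(volumetric_image(v, aff), "positive")
  expect_equal(length(pl$value), 2L)
  expect_setequal(pl$loc_mm[, 1], c(1, 3))
})

test_that("neighbouring equal values (plateaus) are not maxima", {
  v <- array(0, c(4, 3, 3))
  v[2, 2, 2] <- 5
  v[3, 2, 2] <- 5
  pl <- find_local_maxima(volumetric_image(v, diag(4)), "positive")
  expect_equal(length(pl$value), 0L)
})

test_that("constant images yield no peaks and an empty mask errors", {
  v <- array(1, c(4, 4, 4))
  expect_length(find_local_maxima(volumetric_image(v, diag(4)))$value, 0L)
  mask <- array(FALSE, c(4, 4, 4))
  expect_error(find_local_maxima(volumetric_image(v, diag(4), mask)),
               "mask")
})

test_that("negating the image and swapping sign yields the same peak set", {
  set.seed(7)
  v <- array(rnorm(6^3), c(6, 6, 6))
  img_pos <- volumetric_image(v, diag(4))
  img_neg <- volumetric_image(-v, diag(4))
  a <- find_local_maxima(img_pos, "positive")
  b <- find_local_maxima(img_neg, "negative")
  expect_equal(a$loc_mm, b$loc_mm)
  expect_equal(a$value, -b$value)
})

test_that("translating the affine translates peak locations exactly", {
  set.seed(8)
  v <- array(rnorm(6^3), c(6, 6, 6))
  aff1 <- rbind(cbind(diag(2, 3), c(0, 0, 0)), c(0, 0, 0, 1))
  aff2 <- aff1
  aff2[1:3, 4] <- c(5, -7, 11)
  a <- find_local_maxima(volumetric_image(v, aff1))
  b <- find_local_maxima(volumetric_image(v, aff2))
  expect_equal(sweep(a$loc_mm, 2, -c(5, -7, 11)), b$loc_mm)
})

test_that("maxima on the mask edge are reportable", {
  v <- array(0, c(3, 3, 3))
  v[1, 1, 1] <- 2   # corner of the volume
  v[3, 3, 3] <- 1
  pl <- find_local_maxima(volumetric_image(v, diag(4)), "positive")
  expect_true(any(pl$loc_mm[, 1] == 0 & pl$loc_mm[, 2] == 0 &
                  pl$loc_mm[, 3] == 0))
})

test_that("wrong-sign peaks are kept unless sign consistency is required", {
  v <- array(-10, c(5, 3, 3))
  v[2, 2, 2] <- -1   # a local maximum with a negative value
  img <- volumetric_image(v, diag(4))
  expect_gte(length(find_local_maxima(img, "positive")$value), 1L)
  expect_length(
    find_local_maxima(img, "positive", require_sign_consistent = TRUE)$value,
    0L)
})

test_that("top_m clamps, preserves order, and flags shortfall", {
  pl <- peak_list("p1", matrix(seq_len(30), 10, 3), 10:1)
  t5 <- top_m(pl, 5)
  expect_equal(t5$rank, 1:5)
  expect_equal(t5$value, 10:6)
  expect_equal(attr(t5, "shortfall"), 0L)
  t15 <- top_m(pl, 15)
  expect_equal(length(t15$value), 10L)
  expect_equal(attr(t15, "shortfall"), 5L)
  # m = 1 is the image maximum only
  expect_equal(top_m(pl, 1)$value, 10)
})

test_that("peak tables round-trip losslessly with ranks recomputed", {
  set.seed(9)
  pls <- random_peaklists(3, 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_peak_table(pls, path)
  back <- read_peak_table(path)
  expect_equal(length(back), 3L)
  for (i in 1:3) {
    expect_equal(back[[i]]$loc_mm, pls[[i]]$loc_mm)
    expect_equal(back[[i]]$value, pls[[i]]$value)
    expect_equal(back[[i]]$rank, seq_along(back[[i]]$value))
  }
  # missing columns are rejected
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("participant\tx_mm\ty_mm", "p1\t1\t2"), bad)
  expect_error(read_peak_table(bad), "columns")
})

test_that("NIfTI round-trip preserves values and affine", {
  set.seed(10)
  v <- array(rnorm(4^3), c(4, 4, 4))
  aff <- rbind(cbind(diag(10, 3), c(-15, -20, -5)), c(0, 0, 0, 1))
  img <- volumetric_image(v, aff)
  path <- withr::local_tempfile(fileext = ".nii")
  write_stat_image(img, path)
  back <- read_stat_image(path)
  expect_equal(back$values, v, tolerance = 1e-6)
  expect_equal(unname(back$affine), unname(aff), tolerance = 1e-5)
})
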