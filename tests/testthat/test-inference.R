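test_that("rank shuffling keeps locations fixed and draws uniform subsets", {
  set.seed(61)
  pl <- peak_list("p1", matrix(rnorm(30), 10, 3), runif(10))
  single <- peak_list("p2", matrix(1:3, 1, 3), 0.5)
  perm <- permute_ranks(list(pl, single))
  # a single-peak list is unchanged
  expect_equal(perm[[2]]$loc_mm, single$loc_mm)
  # the multiset of locations is invariant
  expect_equal(perm[[1]]$loc_mm[order(perm[[1]]$value), ],
               pl$loc_mm[order(pl$value), ])
  # each of the P peaks lands in the top m with frequency ~ m/P
  m <- 3; P <- 10; B <- 2000
  hits <- numeric(P)
  key <- apply(pl$loc_mm, 1, paste, collapse = ",")
  for (b in seq_len(B)) {
    drawn <- top_m(permute_ranks(list(pl))[[1]], m)
    kd <- apply(drawn$loc_mm, 1, paste, collapse = ",")
    hits[match(kd, key)] <- hits[match(kd, key)] + 1
  }
  freq <- hits / B
  se <- sqrt((m / P) * (1 - m / P) / B)
  expect_true(all(abs(freq - m / P) < 5 * se))
})

test_that("permutation p-values follow the add-one rule and are monotone", {
  set.seed(62)
  pls <- random_peaklists(5, 8)
  null <- build_null(pls, m = 3, n_min = 3, K = 100, seed = 63)
  expect_s3_class(null, "null_distribution")
  expect_equal(dim(null$radii), c(100L, 3L))
  r5 <- null$radii[, "5"]
  # smaller than every null radius -> 1/(K+1); larger than all -> 1
  expect_equal(p_value(min(r5, na.rm = TRUE) - 1, null, n = 5), 1 / 101)
  expect_equal(p_value(max(r5, na.rm = TRUE) + 1, null, n = 5), 1)
  # direct counting oracle at an interior radius
  obs <- unname(quantile(r5, 0.3, na.rm = TRUE))
  expect_equal(p_value(obs, null, n = 5),
               (1 + sum(r5 <= obs, na.rm = TRUE)) / 101)
  # monotone non-decreasing in the observed radius
  grid_r <- seq(min(r5, na.rm = TRUE), max(r5, na.rm = TRUE), length.out = 20)
  ps <- vapply(grid_r, p_value, numeric(1), null = null, n = 5)
  expect_true(all(diff(ps) >= 0))
  expect_error(p_value(1, null, n = 2), "subgroup")
})

test_that("the log2-doubling Bonferroni threshold matches its closed form", {
  # scanning 2..40 at family alpha 0.05
  expect_equal(signif(corrected_alpha(0.05, 2, 40), 2), 0.0094)
  # a single M needs no correction
  expect_equal(corrected_alpha(0.05, 2, 2), 0.05)
  # the 2..30 scan
  expect_equal(corrected_alpha(0.05, 2, 30), 0.05 / (1 + log2(15)))
  # invariant under common scaling of the bounds
  expect_equal(corrected_alpha(0.05, 2, 40), corrected_alpha(0.05, 6, 120))
  expect_error(corrected_alpha(0.05, 3, 2))
  expect_error(corrected_alpha(0.05, 0, 2))
})

test_that("the J heuristic reduces to M when R is zero and finds knees", {
  m <- 2:30
  # R identically zero: J = M, minimised at the first M
  flat <- matrix(0, length(m), 1)
  h0 <- heuristic_J(flat, m = m)
  expect_equal(h0$J[, 1], m)
  expect_equal(unname(h0$m_opt), 2)
  # J strictly increasing in M wherever R is constant
  const <- matrix(25, length(m), 1)
  expect_true(all(diff(heuristic_J(const, m = m)$J[, 1]) > 0))
  # synthetic curve with a known knee: R = 100/M gives J^2 = M^2 + 1e4/M^2,
  # minimised at M = 10
  knee <- matrix(100 / m, length(m), 1)
  expect_equal(unname(heuristic_J(knee, m = m)$m_opt), 10)
})

test_that("a planted cluster is detected and reported coherently", {
  pls <- make_fixture(8, 15, jitter_sd_mm = 3, participation = 1,
                      true_rank_max = 2, seed = 64)
  scan <- peakclust(pls, m_start = 2, m_end = 4, n_min = 5, perms = 99,
                    seed = 65)
  expect_s3_class(scan, "peakclust")
  expect_true(any(scan$table$significant))
  reg <- reported_regions(scan)
  expect_gte(nrow(reg), 1L)
  # the reported region sits at the planted centre
  d <- sqrt(sum((unlist(reg[1, c("x", "y", "z")]) - c(52, -29, 13))^2))
  expect_lt(d, 10)
  # reporting preference: no other collapsed row can beat row order
  expect_true(all(reg$p < scan$threshold))
  # significance flags agree with the threshold
  expect_equal(scan$table$significant, scan$table$p < scan$threshold)
})
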