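test_that("ECDF steps match brute-force counting", {
  tab <- ecdf_table(c(1, 2, 3))
  expect_equal(tab$fraction[tab$value == 2], 2 / 3)
  const <- ecdf_table(rep(4.2, 10))
  expect_equal(nrow(const), 1L)
  expect_equal(const$fraction, 1)
  set.seed(301)
  v <- round(stats::rnorm(200), 1)       # ties on purpose
  tab <- ecdf_table(v)
  expect_equal(tab$fraction[nrow(tab)], 1)
  for (q in sample(v, 100)) {
    expect_equal(tab$fraction[max(which(tab$value <= q))],
                 mean(v <= q))
  }
  expect_error(ecdf_table(numeric(0)), "finite value")
})

test_that("Mann-Whitney exact cases and degenerate inputs behave as specified", {
  r <- mann_whitney_u(c(1, 2), c(1, 2))
  expect_equal(r$U, 2)                   # n1*n2/2 under full symmetry
  expect_equal(r$p_two_sided, 1)

  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_identical(r$method, "exact")
  expect_equal(r$U, 0)
  expect_equal(r$p_two_sided, 0.1)       # 2 of the 20 assignments as extreme

  d <- mann_whitney_u(rep(3, 5), rep(3, 7))
  expect_identical(d$method, "degenerate")
  expect_equal(d$p_two_sided, 1)
})

test_that("exact enumeration equals the pair-counting oracle, with ties", {
  set.seed(302)
  for (i in 1:25) {
    x <- sample(1:5, 4, replace = TRUE)  # heavy ties
    y <- sample(1:5, 4, replace = TRUE)
    r <- mann_whitney_u(x, y)
    if (r$method == "degenerate") next
    expect_identical(r$method, "exact")
    expect_equal(r$p_two_sided, enum_mwu_p(x, y), tolerance = 1e-12,
                 label = paste("case", i))
  }
})

test_that("exact p agrees with wilcox.test's exact p when there are no ties", {
  set.seed(303)
  for (i in 1:40) {
    x <- stats::rnorm(sample(3:8, 1))
    y <- stats::rnorm(sample(3:8, 1))
    expect_equal(mann_whitney_u(x, y)$p_two_sided,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("normal approximation matches wilcox.test's corrected approximation", {
  set.seed(304)
  for (i in 1:20) {
    x <- round(stats::rnorm(30), 1)      # some ties
    y <- round(stats::rnorm(25, 0.3), 1)
    r <- mann_whitney_u(x, y)
    expect_identical(r$method, "normal_approx")
    expect_equal(r$p_two_sided,
                 suppressWarnings(
                   stats::wilcox.test(x, y, exact = FALSE,
                                      correct = TRUE)$p.value),
                 tolerance = 1e-10)
  }
})

test_that("U reflects under group relabel and U_x + U_y = n1*n2", {
  set.seed(305)
  for (i in 1:20) {
    x <- round(stats::rnorm(12), 1); y <- round(stats::rnorm(9), 1)
    rxy <- mann_whitney_u(x, y); ryx <- mann_whitney_u(y, x)
    expect_equal(rxy$U + ryx$U, length(x) * length(y))
    expect_equal(rxy$p_two_sided, ryx$p_two_sided, tolerance = 1e-12)
  }
})

test_that("MWU p decreases monotonically with an elementwise shift", {
  set.seed(306)
  x <- stats::rnorm(60)
  p_prev <- Inf
  for (c_shift in c(0.25, 0.5, 1, 2)) {
    p <- mann_whitney_u(x + c_shift, x)$p_two_sided
    expect_lt(p, p_prev)
    p_prev <- p
  }
  cs <- cumulative_shift(x + 1, x)
  expect_gt(cs$median_shift, 0)          # right shift reported as positive
})

test_that("fold-change classes reproduce the printed up/down ratios", {
  expect_equal(fold_change_ratio(1131, 739)$ratio_up_down_printed, 1.53)
  expect_equal(fold_change_ratio(2221, 760)$ratio_up_down_printed, 2.92)
  expect_equal(fold_change_ratio(1108, 528)$ratio_up_down_printed, 2.10)
  expect_equal(fold_change_ratio(186, 20)$ratio_up_down_printed, 9.3)
  expect_true(is.na(fold_change_ratio(5, 0)$ratio_up_down))
})

test_that("fold-change thresholds are inclusive and identity gives no calls", {
  v1 <- c(1, 1, 1, 1)
  v2 <- c(2, 0.5, 1.99, 1)
  fc <- fold_change_classes(v2, v1, threshold_fold = 2)
  expect_equal(fc$n_up, 1L)              # exactly 2-fold counts as up
  expect_equal(fc$n_down, 1L)
  same <- fold_change_classes(v1, v1, threshold_fold = 2)
  expect_equal(same$n_up + same$n_down, 0L)
  expect_error(fold_change_classes(v2, v1, threshold_fold = 1), "> 1")
})

test_that("overlap statistics reproduce the printed percentages", {
  ov <- overlap_from_counts(11084, 13176, 7638)
  expect_equal(ov$pct_of_a_printed, 68.9)
  expect_equal(ov$pct_of_b_printed, 58.0)
  eq <- overlap_stats(letters, letters)
  expect_equal(c(eq$pct_of_a_printed, eq$pct_of_b_printed), c(100, 100))
  dj <- overlap_stats(c("a", "b"), c("c", "d"))
  expect_equal(c(dj$pct_of_a, dj$pct_of_b), c(0, 0))
  expect_error(overlap_from_counts(3, 3, 4), "exceeds")
})

test_that("Pearson r matches the direct formula and cor.test", {
  x <- 1:10
  expect_equal(pearson_r(x, x)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  set.seed(307)
  for (i in 1:10) {
    a <- stats::rnorm(50); b <- 0.4 * a + stats::rnorm(50)
    got <- pearson_r(a, b)
    want <- stats::cor.test(a, b)
    expect_equal(got$r, unname(want$estimate), tolerance = 1e-12)
    expect_equal(got$p_two_tailed, want$p.value, tolerance = 1e-12)
  }
  expect_error(pearson_r(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson_r(1:2, 2:1), "at least 3")
})

test_that("report rounding is half away from zero", {
  expect_equal(round_half_up(2.125, 2), 2.13)
  expect_equal(round_half_up(-2.125, 2), -2.13)
  expect_equal(round_half_up(57.95, 1), 58.0)
  expect_equal(round_half_up(0.5), 1)
})
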