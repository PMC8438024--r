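test_that("enrichment score is extremal for top-m and bottom-m signatures", {
  set.seed(601)
  expr <- stats::setNames(sort(stats::runif(8), decreasing = TRUE),
                          paste0("g", 1:8))
  combos <- combn(names(expr), 3)
  scores <- apply(combos, 2, function(sig)
    sample_enrichment_score(expr, sig))
  top <- names(sort(expr, decreasing = TRUE))[1:3]
  bottom <- names(sort(expr))[1:3]
  i_top <- which(apply(combos, 2, function(s) setequal(s, top)))
  i_bottom <- which(apply(combos, 2, function(s) setequal(s, bottom)))
  expect_equal(scores[i_top], max(scores))
  expect_equal(scores[i_bottom], min(scores))
  expect_gt(scores[i_top], 0)
  expect_lt(scores[i_bottom], 0)
})

test_that("score is rank-based: identical samples and monotone transforms", {
  set.seed(602)
  expr <- stats::setNames(stats::rnorm(50), paste0("g", 1:50))
  sig <- sample(names(expr), 8)
  s1 <- sample_enrichment_score(expr, sig)
  expect_equal(sample_enrichment_score(expr, sig), s1)
  expect_equal(sample_enrichment_score(exp(expr), sig), s1)
  expect_equal(sample_enrichment_score(expr * 100 + 3, sig), s1)
})

test_that("score errors name missing signature genes", {
  expr <- stats::setNames(1:5, paste0("g", 1:5))
  expect_error(sample_enrichment_score(expr, c("nope1", "nope2")),
               "nope1")
})

test_that("normalisation centres, preserves ranking and rejects degenerates", {
  raw <- c(3, -1, 5, 0.5)
  z <- normalize_scores(raw)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z), 1, tolerance = 1e-12)
  expect_identical(order(z), order(raw))
  expect_error(normalize_scores(rep(2, 4)), "zero variance")
  expect_error(normalize_scores(1), ">= 2 samples")
})

test_that("cohort split labels every sample and flips under negation", {
  set.seed(603)
  mat <- matrix(stats::rlnorm(50 * 12, 4, 1), nrow = 50,
                dimnames = list(paste0("g", 1:50), paste0("s", 1:12)))
  sig <- paste0("g", 1:6)
  sc <- score_cohort(mat, sig)
  expect_setequal(sc$group, c("high", "low"))
  expect_identical(sc$group, ifelse(sc$normalized_score > 0, "high", "low"))
  flipped <- ifelse(-sc$normalized_score > 0, "high", "low")
  # every sample flips label unless its score is exactly 0 (labelled low)
  expect_true(all((sc$group == "high") == (flipped == "low") |
                    sc$normalized_score == 0))
})

test_that("target summary equals the direct two-step z-score computation", {
  set.seed(604)
  mat <- matrix(stats::rlnorm(30 * 10, 4, 1), nrow = 30,
                dimnames = list(paste0("g", 1:30), paste0("s", 1:10)))
  expr <- data.frame(gene_id = rownames(mat), mat, stringsAsFactors = FALSE)
  names(expr) <- c("gene_id", colnames(mat))
  genes <- paste0("g", c(2, 7, 19))
  got <- target_expression_summary(expr, genes)
  lg <- log2(mat[genes, ] + 1)
  z <- t(scale(t(lg)))
  expect_equal(unname(got), unname(colMeans(z)), tolerance = 1e-12)
  # one gene: summary equals that gene's z-scores
  one <- target_expression_summary(expr, "g5")
  z5 <- scale(log2(mat["g5", ] + 1))[, 1]
  expect_equal(unname(one), unname(z5), tolerance = 1e-12)
  # duplicated identical columns behave like a single gene
  mat2 <- rbind(mat, gdup = mat["g5", ])
  expect_equal(unname(target_expression_summary(mat2, c("g5", "gdup"))),
               unname(z5), tolerance = 1e-12)
})

test_that("score-target correlation is exact for self and null for noise", {
  set.seed(605)
  mat <- matrix(stats::rlnorm(80 * 30, 4, 1), nrow = 80,
                dimnames = list(paste0("g", 1:80), paste0("s", 1:30)))
  sc <- score_cohort(mat, paste0("g", 1:10))
  self <- stats::setNames(sc$normalized_score, sc$sample_id)
  res <- score_target_correlation(sc, self)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_gt(res$group_means[["high"]], res$group_means[["low"]])
  noise <- stats::setNames(stats::rnorm(30), sc$sample_id)
  res0 <- score_target_correlation(sc, noise)
  expect_lt(abs(res0$r), 0.5)
})

test_that("scores recover the simulated hypoxia gradient", {
  cfg <- simulation_config(n_cohort_samples = 120L, signature_effect = 2,
                           noise_sd = 0.3, n_background_genes = 150L,
                           n_signature_genes = 25L, rng_seed = 21L)
  sig <- sprintf("sig_%02d", 1:25)
  tgt <- sprintf("tg_%02d", 1:40)
  cohort <- simulate_cohort(cfg, sig, tgt)
  sc <- score_cohort(cohort$fpkm, sig)
  rho <- stats::cor(sc$normalized_score, cohort$hypoxia[sc$sample_id],
                    method = "spearman")
  expect_gt(rho, 0.8)
  # null: with all effect parameters 0 the score is uncorrelated with
  # the latent gradient (a coupled target set would displace signature
  # ranks, so the null zeroes gamma_abundance too)
  cfg0 <- simulation_config(n_cohort_samples = 120L, signature_effect = 0,
                            gamma_abundance = 0,
                            noise_sd = 0.3, n_background_genes = 150L,
                            n_signature_genes = 25L, rng_seed = 22L)
  cohort0 <- simulate_cohort(cfg0, sig, tgt)
  sc0 <- score_cohort(cohort0$fpkm, sig)
  expect_lt(abs(stats::cor(sc0$normalized_score,
                           cohort0$hypoxia[sc0$sample_id])), 0.25)
})
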