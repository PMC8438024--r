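test_that("configuration validation catches bad inputs", {
  expect_error(simulation_config(site_type_probs = c(
    "8mer" = 0.5, "7mer-m8" = 0.2, "7mer-A1" = 0.2, "6mer" = 0.2,
    "none" = 0)), "sum to 1")
  expect_error(simulation_config(site_type_probs = c(a = 1)), "named over")
  expect_error(simulation_config(utr_len_range = c(8L, 50L)),
               "at least 10 nt")
  expect_error(simulation_config(utr_len_range = c(100L, 50L)),
               "min <= max")
  expect_error(simulation_config(n_mirnas = 1L), ">= 2")
  expect_error(simulation_config(gc_content = 1.2), "gc_content")
  expect_error(simulation_config(noise_sd = -1), "noise_sd")
})

test_that("site strength encodes the seed-class ordering", {
  expect_equal(site_strength(c("8mer", "7mer-m8", "7mer-A1", "6mer", "none")),
               c(3L, 2L, 2L, 1L, 0L))
})

test_that("same config and seed give byte-identical emitted files", {
  cfg <- small_sim_config(rng_seed = 31L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_study(simulate_study(cfg), d1)
  write_study(simulate_study(cfg), d2)
  files <- list.files(d1)
  expect_gt(length(files), 5)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("every implanted site is recovered with exact type and coordinates", {
  for (seed in c(32L, 33L)) {
    cfg <- small_sim_config(rng_seed = seed)
    tr <- generate_transcriptome(cfg)
    sites <- scan_all_sites(tr$utrs, tr$mirnas)
    expect_identical(sort(site_key(sites)), sort(site_key(tr$truth$sites)))
  }
  # degenerate all-8mer configuration: one 8mer per transcript, nothing else
  cfg8 <- simulation_config(
    n_transcripts = 50L, n_mirnas = 6L, utr_len_range = c(60L, 120L),
    site_type_probs = c("8mer" = 1, "7mer-m8" = 0, "7mer-A1" = 0,
                        "6mer" = 0, "none" = 0), rng_seed = 34L)
  tr8 <- generate_transcriptome(cfg8)
  s8 <- scan_all_sites(tr8$utrs, tr8$mirnas)
  expect_equal(nrow(s8), 50L)
  expect_true(all(s8$site_type == "8mer"))
  expect_identical(sort(site_key(s8)), sort(site_key(tr8$truth$sites)))
})

test_that("miRNA counts without effects or noise have zero fold change", {
  cfg <- small_sim_config(frac_mirna_reduced = 0, noise_sd = 0,
                          rng_seed = 35L)
  tr <- generate_transcriptome(cfg)
  counts <- simulate_mirna_counts(cfg, tr$truth)
  prof <- mirna_profiles(counts)
  expect_true(all(prof$log2fc == 0))
})

test_that("reduced miRNAs carry the configured fold change plus a shared compositional offset", {
  cfg <- small_sim_config(frac_mirna_reduced = 0.25, lfc_reduced = -2,
                          noise_sd = 0, rng_seed = 36L)
  tr <- generate_transcriptome(cfg)
  counts <- simulate_mirna_counts(cfg, tr$truth)
  # oracle: expected TPM computed directly from the emitted counts
  tpm1 <- 1e6 * counts$cond1 / sum(counts$cond1)
  tpm2 <- 1e6 * counts$cond2 / sum(counts$cond2)
  lfc <- log2(tpm2 / tpm1)
  reduced <- tr$truth$mirna_class[counts$mirna_id] == "reduced"
  offset <- mean(lfc[!reduced])
  # count rounding perturbs the -2 slightly; the classes stay separated
  expect_equal(mean(lfc[reduced]) - offset, -2, tolerance = 0.05)
  expect_lt(max(lfc[reduced]), min(lfc[!reduced]))
  # thresholding recovers the partition exactly
  prof <- mirna_profiles(counts)
  called <- prof$log2fc <= -1
  expect_identical(unname(called), unname(reduced))
})

test_that("fold-change noise averages out as Gaussian propagation predicts", {
  cfg <- small_sim_config(frac_mirna_reduced = 0, noise_sd = 0.1,
                          rng_seed = 37L)
  tr <- generate_transcriptome(cfg)
  n_reps <- 100
  lfc_sum <- 0
  for (r in seq_len(n_reps)) {
    counts <- simulate_mirna_counts(cfg, tr$truth, seed = 2000L + r)
    prof <- mirna_profiles(counts)
    lfc_sum <- lfc_sum + prof$log2fc
  }
  mean_abs <- mean(abs(lfc_sum / n_reps))
  expect_lt(mean_abs, 3 * (0.1 * sqrt(2)) / sqrt(n_reps))
})

test_that("noiseless stress model reads out exactly", {
  cfg <- small_sim_config(noise_sd = 0, delta_binding = 1,
                          gamma_abundance = 0.5, rng_seed = 38L)
  tr <- generate_transcriptome(cfg)
  sim <- simulate_rip_and_expression(tr$transcripts$transcript_id,
                                     tr$truth$strength, cfg)
  s <- tr$truth$strength
  rip_lfc <- condition_log2_ratio(sim$rip)
  expect_equal(unname(rip_lfc), -as.numeric(s), tolerance = 1e-12)
  ab_lfc <- condition_log2_ratio(sim$fpkm)
  expect_equal(unname(ab_lfc), 0.5 * as.numeric(s), tolerance = 1e-12)
})

test_that("mean target shift is non-decreasing in delta_binding", {
  shifts <- vapply(c(0, 0.5, 1), function(delta) {
    cfg <- small_sim_config(noise_sd = 0, delta_binding = delta,
                            rng_seed = 39L)
    tr <- generate_transcriptome(cfg)
    sim <- simulate_rip_and_expression(tr$transcripts$transcript_id,
                                       tr$truth$strength, cfg)
    lr <- condition_log2_ratio(sim$rip)
    s <- tr$truth$strength
    mean(lr[s == 0]) - mean(lr[s > 0])   # attenuation: targets shift left
  }, numeric(1))
  expect_true(all(diff(shifts) >= 0))
})

test_that("cohort generation is deterministic and shapes are consistent", {
  cfg <- small_sim_config(rng_seed = 40L)
  a <- simulate_cohort(cfg, c("s1", "s2"), c("t1", "t2"))
  b <- simulate_cohort(cfg, c("s1", "s2"), c("t1", "t2"))
  expect_identical(a, b)
  expect_equal(ncol(a$fpkm) - 1L, cfg$n_cohort_samples)
  expect_equal(length(a$hypoxia), cfg$n_cohort_samples)
  expect_true(all(a$hypoxia >= 0 & a$hypoxia <= 1))
  expect_error(simulate_cohort(cfg, character(0), "t1"), "non-empty")
})
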