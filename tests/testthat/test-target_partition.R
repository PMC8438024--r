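test_that("expression filters follow the stated inequalities exactly", {
  expr <- data.frame(
    gene_id = c("presence_fail", "mean_fail", "boundary", "ok",
                "presence_boundary"),
    cond1 = c(0.5, 20, 30, 80, 1),
    cond2 = c(100, 20, 30, 90, 100), stringsAsFactors = FALSE)
  kept <- apply_expression_filters(expr)
  # presence is strict (> 1), so FPKM exactly 1 fails; mean is non-strict
  expect_setequal(kept, c("boundary", "ok"))
})

toy_sites <- data.frame(
  transcript_id = c("only_nd", "both", "both", "red_only", "nd_two",
                    "nd_two"),
  mirna_id = c("nd1", "nd1", "red1", "red1", "nd1", "nd2"),
  site_type = c("8mer", "6mer", "6mer", "7mer-m8", "6mer", "6mer"),
  start = c(1L, 1L, 20L, 1L, 1L, 30L),
  end = c(8L, 6L, 25L, 7L, 6L, 35L), stringsAsFactors = FALSE)

toy_selection <- list(non_difference = c("nd1", "nd2"), reduced = "red1")

test_that("exclusive targets require non-difference sites and no reduced sites", {
  tgt <- build_exclusive_targets(toy_sites, toy_selection)
  expect_setequal(tgt, c("only_nd", "nd_two"))
  expect_setequal(
    build_exclusive_targets(toy_sites, toy_selection, universe = "only_nd"),
    "only_nd")
})

test_that("non-targets have zero sites for every expressed miRNA", {
  universe <- c("only_nd", "both", "red_only", "nd_two", "clean1", "clean2")
  nt <- build_non_targets(toy_sites, c("nd1", "nd2", "red1"), universe)
  expect_setequal(nt, c("clean1", "clean2"))
  # a single 6mer for any expressed miRNA disqualifies
  expect_false("red_only" %in% nt)
})

test_that("single-site strata keep only count-1 transcripts, collapsed", {
  strata <- stratify_single_site(toy_sites, toy_selection,
                                 exclusive_targets = c("only_nd", "nd_two"))
  expect_setequal(strata[["8mer"]], "only_nd")
  expect_length(strata[["6mer"]], 0L)      # nd_two has two sites
  expect_length(strata[["7mer"]], 0L)
})

test_that("an all-none generator yields only non-targets downstream", {
  cfg <- small_sim_config(
    site_type_probs = c("8mer" = 0, "7mer-m8" = 0, "7mer-A1" = 0,
                        "6mer" = 0, "none" = 1),
    rng_seed = 11L)
  tr <- generate_transcriptome(cfg)
  expect_equal(nrow(tr$truth$sites), 0L)
  sites <- scan_all_sites(tr$utrs, tr$mirnas)
  expect_equal(nrow(sites), 0L)
  universe <- tr$transcripts$transcript_id
  sel <- list(non_difference = names(tr$mirnas)[1:5],
              reduced = character(0))
  expect_length(build_exclusive_targets(sites, sel, universe), 0L)
  expect_setequal(build_non_targets(sites, names(tr$mirnas), universe),
                  universe)
})

test_that("on synthetic data the partition equals the ground truth", {
  cfg <- small_sim_config(noise_sd = 0.2, rng_seed = 12L)
  tr <- generate_transcriptome(cfg)
  counts <- simulate_mirna_counts(cfg, tr$truth)
  ripex <- simulate_rip_and_expression(tr$transcripts$transcript_id,
                                       tr$truth$strength, cfg)
  sites <- scan_all_sites(tr$utrs, tr$mirnas)
  prof <- mirna_profiles(counts)
  sel <- select_mirnas(prof, n = 5, min_tpm = 10)
  part <- build_partition(sites, sel, ripex$fpkm,
                          expressed_mirnas = prof$mirna_id)
  universe <- apply_expression_filters(ripex$fpkm)
  truth_sites <- tr$truth$sites
  nd_hit <- unique(truth_sites$transcript_id[truth_sites$mirna_id %in%
                                               sel$non_difference])
  red_hit <- unique(truth_sites$transcript_id[truth_sites$mirna_id %in%
                                                sel$reduced])
  expect_setequal(part$exclusive_targets,
                  intersect(setdiff(nd_hit, red_hit), universe))
  expect_setequal(part$non_targets,
                  setdiff(universe, truth_sites$transcript_id))
  # partition invariants
  expect_length(intersect(part$exclusive_targets, part$non_targets), 0L)
  all_strata <- unlist(part$single_site_strata)
  expect_true(all(all_strata %in% part$exclusive_targets))
  expect_equal(anyDuplicated(all_strata), 0L)
  tab <- partition_table(part)
  expect_setequal(tab$transcript_id[tab$class == "exclusive_target"],
                  part$exclusive_targets)
})
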