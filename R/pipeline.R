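pipeline_defaults <- function() {
  list(
    simulate = TRUE,
    simulation = list(),            # overrides for simulation_config()
    inputs = list(),                # file paths when simulate = FALSE
    out_dir = "results/pipeline",
    n_non_difference = 10L,
    min_tpm = 100,
    tpm_pseudocount = 1,
    reduced_lfc_threshold = -1,
    presence_min = 1,
    mean_min = 30,
    collapse_7mer = TRUE,
    fold_threshold = 2,
    rip_fc_pseudocount = 0,         # RIP enrichment is > 0 by construction
    fpkm_fc_pseudocount = 0.1,
    rip_bound_min = 2,              # fold enrichment calling a transcript bound
    score_alpha = 0.25,
    min_n_stratum = 10L
  )
}

#' Build a validated pipeline configuration
#'
#' Defaults describe a fully synthetic run; pass `simulate = FALSE` and
#' an `inputs` list of file paths (utrs, mirnas, rip, fpkm,
#' mirna_counts, halflife, signature, cohort_fpkm) to run on real
#' tables. Any `simulation` entries override [simulation_config()]
#' defaults.
#'
#' @param ... named overrides of the defaults.
#' @return config list of class "pipeline_config".
#' @export
pipeline_config <- function(...) {
  cfg <- utils::modifyList(pipeline_defaults(), list(...))
  if (!isTRUE(cfg$simulate)) {
    needed <- c("utrs", "mirnas", "rip", "fpkm", "mirna_counts",
                "halflife", "signature", "cohort_fpkm")
    missing <- setdiff(needed, names(cfg$inputs))
    if (length(missing) > 0L) {
      stop("inputs missing for non-simulated run: ",
           paste(missing, collapse = ", "))
    }
    for (f in needed) {
      if (!file.exists(cfg$inputs[[f]])) {
        stop("input file not found: ", cfg$inputs[[f]], " (", f, ")")
      }
    }
  }
  if (cfg$fold_threshold <= 1) stop("fold_threshold must be > 1")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file; keys as in [pipeline_config()].
#' @return validated pipeline config.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE)
  })
}

log_stage <- function(stage, msg) {
  message(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [", stage, "] ", msg)
}

#' Run the full analysis pipeline
#'
#' Stages: simulate (or load inputs), seed scan, miRNA selection,
#' transcript partition, cumulative-fraction shift statistics
#' (RIP loading and abundance, fold-change classes, bound-set overlap),
#' half-life stratification, hypoxia scoring, report. Every stage
#' writes its declared TSVs under `cfg$out_dir`; the resolved
#' configuration and a JSON report are written alongside. Deterministic
#' given the config (fixed seeds).
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, a list with every stage's in-memory results.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  # --- simulate or load -----------------------------------------------
  truth <- NULL
  cohort_truth <- NULL
  if (isTRUE(cfg$simulate)) {
    sim_cfg <- with_stage("simulate",
                          do.call(simulation_config, cfg$simulation))
    study <- with_stage("simulate", simulate_study(sim_cfg))
    with_stage("simulate", write_study(study, file.path(out, "data")))
    log_stage("simulate", paste0("generated ", length(study$utrs),
                                 " transcripts, ", length(study$mirnas),
                                 " miRNAs"))
    utrs <- study$utrs; mirnas <- study$mirnas
    rip <- study$rip; fpkm <- study$fpkm
    mirna_counts <- study$mirna_counts
    halflife <- stats::setNames(study$transcripts$halflife_hours,
                                study$transcripts$transcript_id)
    signature <- study$signature_genes
    cohort_fpkm <- study$cohort$fpkm
    truth <- study$truth
    cohort_truth <- study$cohort$hypoxia
  } else {
    p <- cfg$inputs
    utrs <- with_stage("load", read_fasta(p$utrs))
    mirnas <- with_stage("load", read_fasta(p$mirnas))
    rip <- with_stage("load", read_rip_tsv(p$rip))
    fpkm <- with_stage("load", read_expression_tsv(p$fpkm))
    mirna_counts <- with_stage("load", read_mirna_counts(p$mirna_counts))
    halflife <- with_stage("load", read_halflife(p$halflife))
    signature <- with_stage("load", read_signature(p$signature))
    cohort_fpkm <- with_stage("load", read_expression_tsv(p$cohort_fpkm))
  }

  # --- seed scan ------------------------------------------------------
  sites <- with_stage("scan", scan_all_sites(utrs, mirnas))
  summary_all <- with_stage("scan",
    summarize_targets(sites, transcript_ids = names(utrs),
                      collapse_7mer = cfg$collapse_7mer))
  write_tsv(sites, file.path(out, "sites.tsv"))
  write_tsv(summary_all, file.path(out, "target_summary.tsv"))
  log_stage("scan", paste0(nrow(sites), " sites on ",
                           length(unique(sites$transcript_id)),
                           " transcripts"))

  # --- miRNA selection ------------------------------------------------
  profiles <- with_stage("select",
    mirna_profiles(mirna_counts, sequences = mirnas,
                   pseudocount = cfg$tpm_pseudocount))
  selection <- with_stage("select",
    select_mirnas(profiles, n = cfg$n_non_difference,
                  min_tpm = cfg$min_tpm,
                  lfc_threshold = cfg$reduced_lfc_threshold))
  write_tsv(profiles, file.path(out, "mirna_profiles.tsv"))
  write_tsv(data.frame(
    mirna_id = c(selection$non_difference, selection$reduced),
    class = c(rep("non_difference", length(selection$non_difference)),
              rep("reduced", length(selection$reduced)))),
    file.path(out, "selection.tsv"))
  log_stage("select", paste0(length(selection$non_difference),
                             " non-difference, ", length(selection$reduced),
                             " reduced miRNAs"))

  # --- transcript partition -------------------------------------------
  expressed_mirnas <- profiles$mirna_id[profiles$tpm_cond1 >= cfg$min_tpm |
                                          profiles$tpm_cond2 >= cfg$min_tpm]
  partition <- with_stage("partition",
    build_partition(sites, selection, fpkm, expressed_mirnas,
                    presence_min = cfg$presence_min,
                    mean_min = cfg$mean_min,
                    collapse_7mer = cfg$collapse_7mer))
  write_tsv(partition_table(partition), file.path(out, "partition.tsv"))
  log_stage("partition", paste0(length(partition$exclusive_targets),
                                " exclusive targets, ",
                                length(partition$non_targets),
                                " non-targets"))

  # --- shift statistics -----------------------------------------------
  shift <- with_stage("shift",
    shift_analysis(rip, fpkm, partition, cfg))
  write_tsv(shift$tests, file.path(out, "tests.tsv"))
  write_tsv(shift$cdf, file.path(out, "cdf_contrasts.tsv"))
  write_tsv(shift$foldchange, file.path(out, "foldchange.tsv"))
  write_tsv(shift$overlap, file.path(out, "overlap.tsv"))
  log_stage("shift", paste0("target vs non-target RIP shift p = ",
                            signif(shift$rip_contrast$test$p_two_sided, 3)))

  # --- half-life strata -----------------------------------------------
  abundance_lr <- condition_log2_ratio(fpkm, cfg$fpkm_fc_pseudocount)
  strata <- with_stage("halflife",
    stratified_shift(abundance_lr, partition$exclusive_targets,
                     partition$non_targets, halflife,
                     min_n = cfg$min_n_stratum))
  write_tsv(strata, file.path(out, "halflife_strata.tsv"))
  log_stage("halflife", paste0(sum(!strata$skipped), " strata tested"))

  # --- hypoxia scoring ------------------------------------------------
  scores <- with_stage("hypoxia-score",
    score_cohort(cohort_fpkm, signature, alpha = cfg$score_alpha))
  measured <- cohort_fpkm$gene_id
  target_set <- intersect(partition$exclusive_targets, measured)
  background_set <- setdiff(intersect(partition$non_targets, measured),
                            signature)
  corr_rows <- list()
  for (set_name in c("targets", "background")) {
    genes <- if (set_name == "targets") target_set else background_set
    if (length(genes) >= 1L) {
      summ <- with_stage("hypoxia-score",
                         target_expression_summary(cohort_fpkm, genes))
      ct <- with_stage("hypoxia-score",
                       score_target_correlation(scores, summ))
      corr_rows[[set_name]] <- data.frame(
        gene_set = set_name, n_genes = length(genes), r = ct$r,
        p_two_tailed = ct$p_two_tailed,
        mean_high = ct$group_means[["high"]],
        mean_low = ct$group_means[["low"]],
        stringsAsFactors = FALSE)
    }
  }
  correlations <- do.call(rbind, corr_rows)
  write_tsv(scores, file.path(out, "hypoxia_scores.tsv"))
  write_tsv(correlations, file.path(out, "score_correlations.tsv"))
  log_stage("hypoxia-score", paste0(sum(scores$group == "high"), " high / ",
                                    sum(scores$group == "low"),
                                    " low samples"))

  # --- report ---------------------------------------------------------
  resolved <- unclass(cfg)
  resolved$package_version <- as.character(utils::packageVersion("agoshift"))
  yaml::write_yaml(resolved, file.path(out, "resolved_config.yaml"))
  report <- list(
    parameters = resolved,
    n_sites = nrow(sites),
    selection = selection,
    n_exclusive_targets = length(partition$exclusive_targets),
    n_non_targets = length(partition$non_targets),
    strata_sizes = lapply(partition$single_site_strata, length),
    rip_shift_p = shift$rip_contrast$test$p_two_sided,
    abundance_shift_p = shift$abundance_contrast$test$p_two_sided,
    halflife = strata,
    n_high = sum(scores$group == "high"),
    n_low = sum(scores$group == "low"),
    correlations = correlations,
    rounding = "percentages 1 decimal, ratios 2 decimals, half away from zero"
  )
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  log_stage("report", paste0("written to ", out))

  invisible(list(cfg = cfg, sites = sites, summary = summary_all,
                 profiles = profiles, selection = selection,
                 partition = partition, shift = shift, strata = strata,
                 scores = scores, correlations = correlations,
                 truth = truth, cohort_truth = cohort_truth))
}

#' Cumulative-fraction shift analyses over a partition
#'
#' Computes the target vs non-target contrast on RIP-loading log2
#' ratios and on abundance (FPKM) log2 ratios, the per-stratum
#' single-site contrasts, 2-fold and 1.5-fold RIP fold-change classes,
#' and the overlap of the per-condition AGO2-bound transcript sets
#' (fold enrichment >= `cfg$rip_bound_min`).
#'
#' @param rip RIP enrichment table (transcript_id, cond1, cond2).
#' @param fpkm expression table (gene_id, cond1, cond2).
#' @param partition output of [build_partition()].
#' @param cfg a [pipeline_config()].
#' @return list with rip_contrast, abundance_contrast, strata_contrasts,
#'   tests/cdf/foldchange/overlap tables.
#' @export
shift_analysis <- function(rip, fpkm, partition, cfg = pipeline_config()) {
  rip_lr <- condition_log2_ratio(rip, cfg$rip_fc_pseudocount)
  ab_lr <- condition_log2_ratio(fpkm, cfg$fpkm_fc_pseudocount)
  tgt <- partition$exclusive_targets
  nt <- partition$non_targets

  rip_contrast <- cumulative_shift(rip_lr[intersect(names(rip_lr), tgt)],
                                   rip_lr[intersect(names(rip_lr), nt)],
                                   "targets", "non_targets")
  abundance_contrast <- cumulative_shift(ab_lr[intersect(names(ab_lr), tgt)],
                                         ab_lr[intersect(names(ab_lr), nt)],
                                         "targets", "non_targets")
  strata_contrasts <- lapply(partition$single_site_strata, function(ids) {
    ids <- intersect(names(ab_lr), ids)
    if (length(ids) < 2L) return(NULL)
    cumulative_shift(ab_lr[ids], ab_lr[intersect(names(ab_lr), nt)],
                     "stratum", "non_targets")
  })

  contrast_row <- function(name, cs) {
    if (is.null(cs)) return(NULL)
    data.frame(contrast = name, n1 = cs$test$n1, n2 = cs$test$n2,
               U = cs$test$U, z = cs$test$z, p = cs$test$p_two_sided,
               method = cs$test$method, median_shift = cs$median_shift,
               stringsAsFactors = FALSE)
  }
  tests <- do.call(rbind, c(
    list(contrast_row("rip_targets_vs_non_targets", rip_contrast),
         contrast_row("abundance_targets_vs_non_targets",
                      abundance_contrast)),
    lapply(names(strata_contrasts), function(s) {
      contrast_row(paste0("abundance_single_", s, "_vs_non_targets"),
                   strata_contrasts[[s]])
    })))

  cdf_rows <- function(name, cs) {
    if (is.null(cs)) return(NULL)
    rbind(data.frame(contrast = name, group = cs$label_a, cs$ecdf_a),
          data.frame(contrast = name, group = cs$label_b, cs$ecdf_b))
  }
  cdf <- do.call(rbind, c(
    list(cdf_rows("rip_targets_vs_non_targets", rip_contrast),
         cdf_rows("abundance_targets_vs_non_targets", abundance_contrast)),
    lapply(names(strata_contrasts), function(s) {
      cdf_rows(paste0("abundance_single_", s, "_vs_non_targets"),
               strata_contrasts[[s]])
    })))

  fc_row <- function(name, fc, threshold) {
    data.frame(comparison = name, threshold_fold = threshold,
               n_up = fc$n_up, n_down = fc$n_down,
               ratio_up_down = fc$ratio_up_down,
               ratio_up_down_printed = fc$ratio_up_down_printed,
               stringsAsFactors = FALSE)
  }
  foldchange <- rbind(
    fc_row("rip_cond2_vs_cond1",
           fold_change_classes(rip$cond2, rip$cond1, cfg$fold_threshold,
                               cfg$rip_fc_pseudocount), cfg$fold_threshold),
    fc_row("rip_cond2_vs_cond1",
           fold_change_classes(rip$cond2, rip$cond1, 1.5,
                               cfg$rip_fc_pseudocount), 1.5),
    fc_row("fpkm_cond2_vs_cond1",
           fold_change_classes(fpkm$cond2, fpkm$cond1, cfg$fold_threshold,
                               cfg$fpkm_fc_pseudocount), cfg$fold_threshold))

  bound1 <- rip$transcript_id[rip$cond1 >= cfg$rip_bound_min]
  bound2 <- rip$transcript_id[rip$cond2 >= cfg$rip_bound_min]
  ov <- overlap_stats(bound1, bound2)
  overlap <- data.frame(set_a = "bound_cond1", set_b = "bound_cond2",
                        n_a = ov$n_a, n_b = ov$n_b,
                        n_intersect = ov$n_intersect,
                        pct_of_a = ov$pct_of_a_printed,
                        pct_of_b = ov$pct_of_b_printed,
                        stringsAsFactors = FALSE)

  list(rip_contrast = rip_contrast, abundance_contrast = abundance_contrast,
       strata_contrasts = strata_contrasts, tests = tests, cdf = cdf,
       foldchange = foldchange, overlap = overlap)
}
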