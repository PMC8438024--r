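#' Apply the expression filters (presence in both samples + mean floor)
#'
#' Keeps genes with FPKM strictly greater than `presence_min` in both
#' conditions and mean FPKM at least `mean_min` (non-strict), matching
#' the printed inequalities of the source filters.
#'
#' @param expr data.frame with `gene_id` and two condition columns (the
#'   first two numeric columns are used).
#' @param presence_min strict per-sample floor (default 1).
#' @param mean_min non-strict mean floor (default 30).
#' @return character vector of surviving gene ids.
#' @export
apply_expression_filters <- function(expr, presence_min = 1, mean_min = 30) {
  num_cols <- names(expr)[vapply(expr, is.numeric, logical(1))]
  if (length(num_cols) < 2L) stop("expression matrix needs >= 2 samples")
  v1 <- expr[[num_cols[1L]]]
  v2 <- expr[[num_cols[2L]]]
  keep <- v1 > presence_min & v2 > presence_min &
    (v1 + v2) / 2 >= mean_min
  expr$gene_id[keep]
}

#' Exclusive targets of the selected non-difference miRNAs
#'
#' Transcripts with at least one seed site for any non-difference miRNA
#' and zero sites for every stress-reduced miRNA.
#'
#' @param sites site table from [scan_all_sites()].
#' @param selection output of [select_mirnas()].
#' @param universe optional transcript ids to restrict to (e.g. the
#'   expression-filtered set).
#' @return character vector of transcript ids.
#' @export
build_exclusive_targets <- function(sites, selection, universe = NULL) {
  nd_hit <- unique(sites$transcript_id[sites$mirna_id %in%
                                         selection$non_difference])
  red_hit <- unique(sites$transcript_id[sites$mirna_id %in%
                                          selection$reduced])
  out <- setdiff(nd_hit, red_hit)
  if (!is.null(universe)) out <- intersect(out, universe)
  out
}

#' Non-target transcripts
#'
#' Transcripts with zero seed sites for every expressed miRNA (not just
#' the selected ten) within the given universe.
#'
#' @param sites site table from [scan_all_sites()].
#' @param expressed_mirnas miRNA ids passing the expression floor.
#' @param universe transcript ids to classify.
#' @return character vector of transcript ids.
#' @export
build_non_targets <- function(sites, expressed_mirnas, universe) {
  hit <- unique(sites$transcript_id[sites$mirna_id %in% expressed_mirnas])
  setdiff(universe, hit)
}

#' Single-site seed-class strata within the exclusive targets
#'
#' Restricted to sites for the non-difference miRNAs, transcripts whose
#' total site count is exactly 1 are keyed by that site's collapsed type.
#'
#' @param sites site table from [scan_all_sites()].
#' @param selection output of [select_mirnas()].
#' @param exclusive_targets output of [build_exclusive_targets()].
#' @param collapse_7mer collapse 7mer-m8/7mer-A1 to "7mer" (default).
#' @return named list of transcript id vectors, one per stratum.
#' @export
stratify_single_site <- function(sites, selection, exclusive_targets,
                                 collapse_7mer = TRUE) {
  summ <- summarize_targets(sites, transcript_ids = exclusive_targets,
                            mirna_subset = selection$non_difference,
                            collapse_7mer = collapse_7mer)
  single <- summ[summ$is_single_site, , drop = FALSE]
  strata_names <- if (collapse_7mer) c("6mer", "7mer", "8mer") else SITE_TYPES
  out <- lapply(strata_names, function(s) {
    single$transcript_id[single$single_site_stratum == s]
  })
  stats::setNames(out, strata_names)
}

#' Build the complete transcript partition
#'
#' @param sites site table over all expressed miRNAs.
#' @param selection output of [select_mirnas()].
#' @param expr expression matrix (two conditions) for filtering.
#' @param expressed_mirnas miRNA ids used for the non-target rule.
#' @param presence_min,mean_min expression filters, see
#'   [apply_expression_filters()].
#' @param collapse_7mer collapse the 7mer flavours in strata labels.
#' @return list with `exclusive_targets`, `non_targets`,
#'   `single_site_strata`, `universe` and `filters`.
#' @export
build_partition <- function(sites, selection, expr, expressed_mirnas,
                            presence_min = 1, mean_min = 30,
                            collapse_7mer = TRUE) {
  universe <- apply_expression_filters(expr, presence_min, mean_min)
  targets <- build_exclusive_targets(sites, selection, universe)
  non_targets <- build_non_targets(sites, expressed_mirnas, universe)
  strata <- stratify_single_site(sites, selection, targets, collapse_7mer)
  list(exclusive_targets = targets, non_targets = non_targets,
       single_site_strata = strata, universe = universe,
       filters = list(presence_min = presence_min, mean_min = mean_min))
}

#' Flatten a partition to a long table (transcript_id, class, stratum)
#'
#' @param partition output of [build_partition()].
#' @return data.frame suitable for `write_tsv()`.
#' @export
partition_table <- function(partition) {
  strat <- rep(NA_character_, length(partition$exclusive_targets))
  for (s in names(partition$single_site_strata)) {
    strat[partition$exclusive_targets %in%
            partition$single_site_strata[[s]]] <- s
  }
  rbind(
    data.frame(transcript_id = partition$exclusive_targets,
               class = "exclusive_target", stratum = strat,
               stringsAsFactors = FALSE),
    data.frame(transcript_id = partition$non_targets,
               class = "non_target", stratum = NA_character_,
               stringsAsFactors = FALSE)
  )
}
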