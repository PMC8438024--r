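#' Normalise miRNA raw counts to TPM (tags per million aligned miRNAs)
#'
#' Per condition, `tpm_i = 1e6 * count_i / sum(counts)`.
#'
#' @param counts data.frame with `mirna_id` and one numeric column per
#'   condition, or a numeric matrix/data.frame of counts.
#' @return object of the same shape with counts replaced by TPM.
#' @export
tpm_normalize <- function(counts) {
  tab <- counts
  num_cols <- names(tab)[vapply(tab, is.numeric, logical(1))]
  if (length(num_cols) == 0L) stop("no numeric count columns")
  for (col in num_cols) {
    v <- tab[[col]]
    if (any(v < 0)) stop("negative count in column '", col, "'")
    s <- sum(v)
    if (s <= 0) stop("all-zero counts in condition '", col, "'")
    tab[[col]] <- 1e6 * v / s
  }
  tab
}

#' Log2 fold change between two TPM values with a pseudocount
#'
#' @param tpm_cond2,tpm_cond1 TPM values (condition 2 vs condition 1).
#' @param pseudocount added to both, must be > 0.
#' @return `log2((tpm_cond2 + pc) / (tpm_cond1 + pc))`.
#' @export
mirna_log2fc <- function(tpm_cond2, tpm_cond1, pseudocount = 1) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  log2((tpm_cond2 + pseudocount) / (tpm_cond1 + pseudocount))
}

#' Build per-miRNA expression profiles from a raw count table
#'
#' @param counts data.frame with columns mirna_id, cond1, cond2.
#' @param sequences optional named vector of mature sequences.
#' @param pseudocount TPM pseudocount for the fold change.
#' @return data.frame with raw counts, TPM per condition and log2fc.
#' @export
mirna_profiles <- function(counts, sequences = NULL, pseudocount = 1) {
  stopifnot(all(c("mirna_id", "cond1", "cond2") %in% names(counts)))
  tpm <- tpm_normalize(counts[, c("mirna_id", "cond1", "cond2")])
  out <- data.frame(
    mirna_id = counts$mirna_id,
    count_cond1 = counts$cond1, count_cond2 = counts$cond2,
    tpm_cond1 = tpm$cond1, tpm_cond2 = tpm$cond2,
    log2fc = mirna_log2fc(tpm$cond2, tpm$cond1, pseudocount),
    stringsAsFactors = FALSE
  )
  if (!is.null(sequences)) out$sequence <- unname(sequences[out$mirna_id])
  out
}

#' Select the top-N non-difference miRNAs
#'
#' Among miRNAs with TPM >= `min_tpm` in both conditions (and not in
#' `exclude`), rank ascending by |log2fc|, break ties by higher mean TPM
#' and then lexicographic id, and return the first N.
#'
#' @param profiles output of [mirna_profiles()].
#' @param n number of miRNAs to select.
#' @param min_tpm expression floor applied to both conditions.
#' @param exclude ids never eligible (e.g. the stress-reduced set).
#' @return character vector of N mirna ids, in rank order.
#' @export
select_non_difference <- function(profiles, n = 10L, min_tpm = 100,
                                  exclude = character()) {
  eligible <- profiles[profiles$tpm_cond1 >= min_tpm &
                         profiles$tpm_cond2 >= min_tpm &
                         !(profiles$mirna_id %in% exclude), , drop = FALSE]
  if (nrow(eligible) < n) {
    stop("only ", nrow(eligible), " miRNAs pass min_tpm = ", min_tpm,
         " in both conditions; ", n, " requested")
  }
  mean_tpm <- (eligible$tpm_cond1 + eligible$tpm_cond2) / 2
  ord <- order(abs(eligible$log2fc), -mean_tpm, eligible$mirna_id)
  eligible$mirna_id[ord][seq_len(n)]
}

#' Select stress-reduced miRNAs
#'
#' miRNAs with log2fc at or below `lfc_threshold` (default -1, i.e. at
#' least 2-fold down) and TPM >= `min_tpm` in condition 1.
#'
#' @param profiles output of [mirna_profiles()].
#' @param lfc_threshold log2 fold-change cut (negative).
#' @param min_tpm expression floor in condition 1.
#' @return character vector of mirna ids.
#' @export
select_reduced <- function(profiles, lfc_threshold = -1, min_tpm = 100) {
  sel <- profiles$log2fc <= lfc_threshold & profiles$tpm_cond1 >= min_tpm
  profiles$mirna_id[sel]
}

#' Build the full miRNA selection (non-difference + reduced sets)
#'
#' The two sets are disjoint by construction: reduced miRNAs are never
#' eligible for the non-difference ranking.
#'
#' @inheritParams select_non_difference
#' @inheritParams select_reduced
#' @return list with `non_difference` (ordered ids), `reduced` (ids) and
#'   `params`.
#' @export
select_mirnas <- function(profiles, n = 10L, min_tpm = 100,
                          lfc_threshold = -1) {
  reduced <- select_reduced(profiles, lfc_threshold, min_tpm)
  non_diff <- select_non_difference(profiles, n, min_tpm, exclude = reduced)
  list(non_difference = non_diff, reduced = reduced,
       params = list(n = n, min_tpm = min_tpm,
                     lfc_threshold = lfc_threshold))
}
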