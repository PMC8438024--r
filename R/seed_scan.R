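#' Canonical seed-site types, strongest first
#'
#' Scan priority is 8mer > 7mer-m8 > 7mer-A1 > 6mer. In single-site
#' stratifications the two 7mer flavours collapse to "7mer".
#' @export
SITE_TYPES <- c("8mer", "7mer-m8", "7mer-A1", "6mer")

site_priority <- function(type) match(type, SITE_TYPES)

#' Extract the miRNA seed region (positions 2-8)
#'
#' @param mirna_seq mature miRNA sequence, 5'->3', RNA alphabet, >= 8 nt.
#' @return the 7-nt subsequence at positions 2-8, 5'->3'.
#' @export
seed_region <- function(mirna_seq) {
  mirna_seq <- normalize_rna(mirna_seq, "miRNA sequence")
  if (nchar(mirna_seq) < 8L) {
    stop("miRNA sequence must be at least 8 nt to define a seed (got ",
         nchar(mirna_seq), ")")
  }
  substr(mirna_seq, 2L, 8L)
}

#' Seed-match patterns for one miRNA
#'
#' The UTR-side (sense strand, 5'->3') match strings for the four
#' canonical site types: an 8mer site is the reverse complement of miRNA
#' positions 2-8 followed by an A (facing miRNA position 1); 7mer-m8 is
#' the reverse complement of positions 2-8; 7mer-A1 is the reverse
#' complement of positions 2-7 plus A; 6mer is the reverse complement of
#' positions 2-7. G:U wobble pairs are not allowed.
#'
#' @param mirna_seq mature miRNA sequence, >= 8 nt.
#' @return named character vector of match strings, names in `SITE_TYPES`.
#' @export
site_patterns <- function(mirna_seq) {
  seed28 <- seed_region(mirna_seq)
  seed27 <- substr(seed28, 1L, 6L)
  c("8mer"    = paste0(rc_rna(seed28), "A"),
    "7mer-m8" = rc_rna(seed28),
    "7mer-A1" = paste0(rc_rna(seed27), "A"),
    "6mer"    = rc_rna(seed27))
}

# all (possibly overlapping) start positions of fixed pattern in subject
locate_all <- function(subject, pattern) {
  loc <- stringi::stri_locate_all_fixed(subject, pattern, overlap = TRUE)[[1L]]
  if (anyNA(loc[, 1L])) integer(0) else loc[, 1L]
}

# greedy site resolution: strongest type first, then left to right;
# accepted sites never overlap, so weaker matches contained in a
# reported stronger site are suppressed
resolve_candidates <- function(cand) {
  cand <- cand[order(site_priority(cand$site_type), cand$start), ,
               drop = FALSE]
  keep <- logical(nrow(cand))
  occ_start <- integer(0)
  occ_end <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (!any(cand$start[i] <= occ_end & cand$end[i] >= occ_start)) {
      keep[i] <- TRUE
      occ_start <- c(occ_start, cand$start[i])
      occ_end <- c(occ_end, cand$end[i])
    }
  }
  out <- cand[keep, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

#' Scan a 3'-UTR for canonical seed-match sites of one miRNA
#'
#' Every matching window is classified with the strongest applicable type
#' (8mer > 7mer-m8 > 7mer-A1 > 6mer); candidate sites are then accepted
#' greedily in strength order, left to right, so that accepted sites for
#' the same miRNA never overlap and weaker matches contained in a
#' reported stronger site are suppressed. Coordinates are 1-based closed
#' intervals on the given UTR, 5'->3'.
#'
#' @param utr_seq 3'-UTR sequence (sense strand).
#' @param mirna_seq mature miRNA sequence, >= 8 nt.
#' @param mirna_id,transcript_id ids copied into the output.
#' @return data.frame with columns transcript_id, mirna_id, site_type,
#'   start, end; ordered by start.
#' @export
scan_sites <- function(utr_seq, mirna_seq, mirna_id = "mirna",
                       transcript_id = "transcript") {
  utr_seq <- normalize_rna(utr_seq, paste0("UTR '", transcript_id, "'"))
  pats <- site_patterns(mirna_seq)
  starts <- lapply(pats, locate_all, subject = utr_seq)
  n <- lengths(starts)
  cand <- data.frame(
    site_type = rep(names(pats), n),
    start     = unlist(starts, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  if (nrow(cand) == 0L) {
    return(data.frame(transcript_id = character(), mirna_id = character(),
                      site_type = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  cand$end <- cand$start + nchar(pats[cand$site_type]) - 1L
  out <- resolve_candidates(cand)
  data.frame(transcript_id = transcript_id, mirna_id = mirna_id,
             site_type = out$site_type, start = out$start, end = out$end,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Scan many UTRs against many miRNAs
#'
#' Vectorised over UTRs per pattern; applies the same greedy
#' strength-then-position resolution as [scan_sites()] within each
#' (transcript, miRNA) pair.
#'
#' @param utrs named character vector of UTR sequences.
#' @param mirnas named character vector of mature miRNA sequences.
#' @return combined site table (see [scan_sites()]), ordered by
#'   transcript, miRNA, start.
#' @export
scan_all_sites <- function(utrs, mirnas) {
  stopifnot(!is.null(names(utrs)), !is.null(names(mirnas)))
  utrs <- vapply(utrs, normalize_rna, character(1), what = "UTR")
  empty <- data.frame(transcript_id = character(), mirna_id = character(),
                      site_type = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  parts <- list()
  k <- 0L
  for (m in names(mirnas)) {
    pats <- site_patterns(mirnas[[m]])
    for (type in names(pats)) {
      loc <- stringi::stri_locate_all_fixed(utrs, pats[[type]],
                                            overlap = TRUE)
      n_hit <- vapply(loc, function(x) sum(!is.na(x[, 1L])), integer(1))
      if (sum(n_hit) == 0L) next
      k <- k + 1L
      parts[[k]] <- data.frame(
        transcript_id = rep(names(utrs), n_hit),
        mirna_id = m,
        site_type = type,
        start = unlist(lapply(loc, function(x) x[!is.na(x[, 1L]), 1L]),
                       use.names = FALSE),
        stringsAsFactors = FALSE)
      parts[[k]]$end <- parts[[k]]$start + nchar(pats[[type]]) - 1L
    }
  }
  if (k == 0L) return(empty)
  cand <- do.call(rbind, parts)
  resolved <- lapply(
    split(cand, list(cand$transcript_id, cand$mirna_id), drop = TRUE),
    resolve_candidates)
  out <- do.call(rbind, resolved)
  out <- out[order(out$transcript_id, out$mirna_id, out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out[, c("transcript_id", "mirna_id", "site_type", "start", "end")]
}

#' Collapse a site type to the field's coarse class (6mer/7mer/8mer)
#'
#' @param site_type character vector of canonical types.
#' @return "6mer", "7mer" or "8mer".
#' @export
collapse_site_type <- function(site_type) {
  ifelse(site_type %in% c("7mer-m8", "7mer-A1"), "7mer", site_type)
}

#' Summarise seed sites per transcript
#'
#' Counts are restricted to `mirna_subset` when given. A transcript is
#' single-site when its total site count over the retained miRNAs is
#' exactly 1; its stratum is that site's collapsed type ("6mer", "7mer",
#' "8mer") when `collapse_7mer` is TRUE (the default), otherwise the
#' canonical type.
#'
#' @param sites site table from [scan_all_sites()].
#' @param transcript_ids transcripts to report (zero-site transcripts are
#'   included with strongest_type "none"); defaults to those in `sites`.
#' @param mirna_subset optional miRNA ids to restrict the counts to.
#' @param collapse_7mer collapse 7mer-m8/7mer-A1 in strata labels.
#' @return data.frame with per-type counts, total_site_count,
#'   strongest_type, is_single_site and single_site_stratum.
#' @export
summarize_targets <- function(sites, transcript_ids = NULL,
                              mirna_subset = NULL, collapse_7mer = TRUE) {
  if (!is.null(mirna_subset)) {
    sites <- sites[sites$mirna_id %in% mirna_subset, , drop = FALSE]
  }
  if (is.null(transcript_ids)) transcript_ids <- unique(sites$transcript_id)
  tt <- table(factor(sites$transcript_id, levels = transcript_ids),
              factor(sites$site_type, levels = SITE_TYPES))
  counts <- as.data.frame.matrix(tt)
  names(counts) <- c("n_8mer", "n_7mer_m8", "n_7mer_a1", "n_6mer")
  total <- rowSums(counts)
  strongest <- rep("none", length(transcript_ids))
  for (type in rev(SITE_TYPES)) {      # weakest first, overwritten by stronger
    col <- c("8mer" = "n_8mer", "7mer-m8" = "n_7mer_m8",
             "7mer-A1" = "n_7mer_a1", "6mer" = "n_6mer")[[type]]
    strongest[counts[[col]] > 0L] <- type
  }
  single <- total == 1L
  stratum <- rep(NA_character_, length(transcript_ids))
  stratum[single] <- strongest[single]
  if (collapse_7mer) stratum <- collapse_site_type(stratum)
  data.frame(transcript_id = transcript_ids, counts,
             total_site_count = as.integer(total),
             strongest_type = strongest,
             is_single_site = single,
             single_site_stratum = stratum,
             stringsAsFactors = FALSE, row.names = NULL)
}
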