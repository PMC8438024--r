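#' Single-sample rank-based signature enrichment score (ssGSEA-style)
#'
#' Genes are ranked descending by expression within the sample (ties
#' broken deterministically by gene id). Walking down the ranked list,
#' signature genes accumulate weight `(N - i + 1)^alpha` (the descending
#' rank raised to alpha) normalised by the signature total, and
#' non-signature genes accumulate `1/(N - m)`. The raw score is the sum
#' over positions of (P_hit - P_miss). Rank-based, so invariant to any
#' within-sample monotone transformation of expression.
#'
#' @param expression named numeric vector (one sample), finite.
#' @param signature character vector of signature gene ids.
#' @param alpha weight exponent (default 0.25).
#' @return raw enrichment score (numeric scalar).
#' @export
sample_enrichment_score <- function(expression, signature, alpha = 0.25) {
  stopifnot(!is.null(names(expression)))
  if (any(!is.finite(expression))) stop("expression must be finite")
  present <- intersect(unique(signature), names(expression))
  if (length(present) == 0L) {
    stop("no signature genes measured; missing: ",
         paste(utils::head(setdiff(signature, names(expression)), 5L),
               collapse = ", "))
  }
  N <- length(expression)
  m <- length(present)
  if (m >= N) stop("signature covers every measured gene")
  ord <- order(-expression, names(expression))
  hit <- names(expression)[ord] %in% present
  w <- (N - seq_len(N) + 1)^alpha
  p_hit <- cumsum(w * hit) / sum(w[hit])
  p_miss <- cumsum(!hit) / (N - m)
  sum(p_hit - p_miss)
}

#' Z-normalise raw enrichment scores across a cohort
#'
#' Supplies the 0 threshold used to split the cohort: subtract the
#' cohort mean and divide by the cohort standard deviation.
#'
#' @param raw_scores numeric vector, length >= 2, non-constant.
#' @return normalised scores (mean 0, sd 1), names preserved.
#' @export
normalize_scores <- function(raw_scores) {
  if (length(raw_scores) < 2L) stop("need >= 2 samples to normalise scores")
  s <- stats::sd(raw_scores)
  if (s == 0) stop("zero variance across raw scores")
  (raw_scores - mean(raw_scores)) / s
}

#' Score a cohort and split it at normalised score 0
#'
#' Samples with normalised score > 0 are labelled "high", the rest
#' (including exactly 0) "low", so every sample is labelled.
#'
#' @param expr data.frame with `gene_id` then one numeric column per
#'   sample (FPKM), or a numeric matrix with gene rownames.
#' @param signature character vector of signature gene ids.
#' @param alpha weight exponent for [sample_enrichment_score()].
#' @return data.frame with sample_id, raw_score, normalized_score, group.
#' @export
score_cohort <- function(expr, signature, alpha = 0.25) {
  mat <- as_gene_matrix(expr)
  raw <- vapply(colnames(mat), function(s) {
    sample_enrichment_score(stats::setNames(mat[, s], rownames(mat)),
                            signature, alpha)
  }, numeric(1))
  norm <- normalize_scores(raw)
  data.frame(sample_id = colnames(mat), raw_score = unname(raw),
             normalized_score = unname(norm),
             group = ifelse(norm > 0, "high", "low"),
             stringsAsFactors = FALSE)
}

#' Per-sample summary of a target gene set's expression
#'
#' Each gene's log2(FPKM + 1) is z-scored across samples; the summary is
#' the per-sample mean of those z-scores.
#'
#' @param expr cohort expression (see [score_cohort()]).
#' @param genes gene ids to summarise (must intersect measured genes).
#' @return named numeric vector, one value per sample.
#' @export
target_expression_summary <- function(expr, genes) {
  mat <- as_gene_matrix(expr)
  genes <- intersect(genes, rownames(mat))
  if (length(genes) == 0L) stop("no summary genes measured")
  lg <- log2(mat[genes, , drop = FALSE] + 1)
  mu <- rowMeans(lg)
  sdv <- apply(lg, 1L, stats::sd)
  keep <- sdv > 0
  if (!any(keep)) stop("all summary genes are constant across samples")
  z <- (lg[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
  colMeans(z)
}

#' Correlate hypoxia scores with a target-set expression summary
#'
#' Pearson correlation (two-tailed t p-value) between normalised scores
#' and the per-sample summary, plus the high-vs-low group contrast on
#' the summary (group means and Mann-Whitney test).
#'
#' @param scores data.frame from [score_cohort()].
#' @param summaries named numeric vector from
#'   [target_expression_summary()], aligned by sample id.
#' @return list with r, p_two_tailed, group_means and group_test.
#' @export
score_target_correlation <- function(scores, summaries) {
  summaries <- summaries[scores$sample_id]
  if (anyNA(summaries)) stop("summaries missing for some scored samples")
  ct <- pearson_r(scores$normalized_score, summaries)
  hi <- summaries[scores$group == "high"]
  lo <- summaries[scores$group == "low"]
  group_test <- if (length(hi) >= 1L && length(lo) >= 1L) {
    mann_whitney_u(hi, lo)
  } else NULL
  list(r = ct$r, p_two_tailed = ct$p_two_tailed,
       group_means = c(high = mean(hi), low = mean(lo)),
       group_test = group_test)
}

# accept either a gene_id-keyed data.frame or a rownamed numeric matrix
as_gene_matrix <- function(expr) {
  if (is.matrix(expr)) {
    stopifnot(!is.null(rownames(expr)), !is.null(colnames(expr)))
    return(expr)
  }
  stopifnot(is.data.frame(expr), "gene_id" %in% names(expr))
  num_cols <- names(expr)[vapply(expr, is.numeric, logical(1))]
  mat <- as.matrix(expr[, num_cols, drop = FALSE])
  rownames(mat) <- expr$gene_id
  mat
}
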