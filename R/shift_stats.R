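#' Empirical cumulative distribution as a step table
#'
#' Right-continuous ECDF over the sorted unique support; the fraction at
#' the maximum is 1.
#'
#' @param values numeric vector with at least one finite value.
#' @return data.frame with columns `value` (sorted unique support) and
#'   `fraction` (cumulative fraction <= value).
#' @export
ecdf_table <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("ecdf_table needs at least one finite value")
  support <- sort(unique(values))
  counts <- tabulate(match(values, support), nbins = length(support))
  data.frame(value = support, fraction = cumsum(counts) / length(values))
}

#' Two-sided Mann-Whitney U test (tie-corrected, exact at small n)
#'
#' Midranks over the pooled sample; `U = R1 - n1(n1+1)/2`. The normal
#' approximation uses the tie-corrected variance
#' `n1*n2/12 * ((N+1) - sum(t^3-t)/(N*(N-1)))` and a continuity
#' correction of 0.5; `p = 2*pnorm(-|z|)` capped at 1. When
#' `n1 + n2 <= exact_max_n` the full permutation distribution of U over
#' all `choose(N, n1)` group assignments is enumerated instead
#' (two-sided as `P(|U - mu| >= |u_obs - mu|)`). If all pooled values
#' are identical the test is degenerate and p = 1.
#'
#' @param x,y numeric samples (n1, n2 >= 1).
#' @param exact_max_n switch to exact enumeration at `n1+n2 <=` this.
#' @return list with U, z, p_two_sided, n1, n2, n_tied_groups and method
#'   ("normal_approx", "exact" or "degenerate").
#' @export
mann_whitney_u <- function(x, y, exact_max_n = 16L) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("both samples must be non-empty")
  pooled <- c(x, y)
  N <- n1 + n2
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  tie_sizes <- table(pooled)
  n_tied_groups <- sum(tie_sizes > 1L)
  mu <- n1 * n2 / 2
  tie_term <- sum(tie_sizes^3 - tie_sizes) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  res <- list(U = U, z = 0, p_two_sided = 1, n1 = n1, n2 = n2,
              n_tied_groups = as.integer(n_tied_groups),
              method = "normal_approx")
  if (sigma2 <= 0) {                      # all pooled values identical
    res$method <- "degenerate"
    return(res)
  }
  d <- U - mu
  z <- (d - sign(d) * min(0.5, abs(d))) / sqrt(sigma2)
  res$z <- z
  if (N <= exact_max_n) {
    combos <- utils::combn(N, n1)
    rank_sums <- colSums(matrix(r[combos], nrow = n1))
    U_all <- rank_sums - n1 * (n1 + 1) / 2
    res$p_two_sided <- mean(abs(U_all - mu) >= abs(d) - 1e-9)
    res$method <- "exact"
  } else {
    res$p_two_sided <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  res
}

#' Classify paired values into fold-change classes and report the ratio
#'
#' Up if `(v2+pc)/(v1+pc) >= threshold_fold`, down if `<= 1/threshold_fold`
#' (both inclusive). `ratio_up_down = n_up / n_down`, reported rounded
#' half-away-from-zero to 2 decimals in `ratio_up_down_printed`; it is
#' undefined (NA) when n_down is 0.
#'
#' @param values_cond2,values_cond1 aligned numeric vectors.
#' @param threshold_fold fold threshold, > 1 (e.g. 2 or 1.5).
#' @param pseudocount added to both values (default 0).
#' @return list with n_up, n_down, ratio_up_down, ratio_up_down_printed.
#' @export
fold_change_classes <- function(values_cond2, values_cond1,
                                threshold_fold = 2, pseudocount = 0) {
  if (threshold_fold <= 1) stop("threshold_fold must be > 1")
  stopifnot(length(values_cond2) == length(values_cond1))
  ratio <- (values_cond2 + pseudocount) / (values_cond1 + pseudocount)
  n_up <- sum(ratio >= threshold_fold)
  n_down <- sum(ratio <= 1 / threshold_fold)
  fold_change_ratio(n_up, n_down)
}

#' Up/down ratio from class counts
#'
#' @param n_up,n_down class counts.
#' @return list with n_up, n_down, ratio_up_down (full precision) and
#'   ratio_up_down_printed (2 decimals, half away from zero).
#' @export
fold_change_ratio <- function(n_up, n_down) {
  ratio <- if (n_down > 0) n_up / n_down else NA_real_
  list(n_up = as.integer(n_up), n_down = as.integer(n_down),
       ratio_up_down = ratio,
       ratio_up_down_printed = round_half_up(ratio, 2L))
}

#' Overlap (Venn) summary of two sets
#'
#' @param set_a,set_b character vectors (treated as sets).
#' @return list with n_a, n_b, n_intersect and percentages of each set
#'   covered by the intersection, printed to 1 decimal.
#' @export
overlap_stats <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  overlap_from_counts(length(a), length(b), length(intersect(a, b)))
}

#' Overlap summary from printed counts
#'
#' @param n_a,n_b,n_intersect set sizes and intersection size.
#' @return list with counts, pct_of_a, pct_of_b (full precision) and the
#'   1-decimal printed forms pct_of_a_printed / pct_of_b_printed.
#' @export
overlap_from_counts <- function(n_a, n_b, n_intersect) {
  if (n_intersect > min(n_a, n_b)) stop("intersection exceeds a set size")
  pa <- if (n_a > 0) 100 * n_intersect / n_a else NA_real_
  pb <- if (n_b > 0) 100 * n_intersect / n_b else NA_real_
  list(n_a = n_a, n_b = n_b, n_intersect = n_intersect,
       pct_of_a = pa, pct_of_b = pb,
       pct_of_a_printed = round_half_up(pa, 1L),
       pct_of_b_printed = round_half_up(pb, 1L))
}

#' Pearson product-moment correlation with two-tailed t p-value
#'
#' `t = r * sqrt((n-2)/(1-r^2))` against the t distribution with n-2
#' degrees of freedom.
#'
#' @param x,y numeric vectors, n >= 3, finite, non-constant.
#' @return list with r, t, df and p_two_tailed.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("pearson_r needs at least 3 paired finite values")
  sx <- x - mean(x); sy <- y - mean(y)
  vx <- sum(sx^2); vy <- sum(sy^2)
  if (vx == 0 || vy == 0) stop("zero variance in pearson_r input")
  r <- sum(sx * sy) / sqrt(vx * vy)
  r <- max(-1, min(1, r))
  if (abs(r) == 1) {
    t <- Inf * sign(r); p <- 0
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), df = n - 2)
  }
  list(r = r, t = t, df = n - 2L, p_two_tailed = p)
}

#' Round half away from zero at a fixed number of decimals
#'
#' Report-layer rounding used for printed percentages and ratios (R's
#' `round()` rounds half to even, which does not match printed tables).
#'
#' @param x numeric.
#' @param digits decimals.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Per-transcript log2 condition ratio from a two-condition table
#'
#' @param tab data.frame with an id column followed by cond1 and cond2.
#' @param pseudocount added to both conditions before the ratio.
#' @return named numeric vector of log2((cond2+pc)/(cond1+pc)).
#' @export
condition_log2_ratio <- function(tab, pseudocount = 0) {
  stopifnot(all(c("cond1", "cond2") %in% names(tab)))
  ids <- tab[[1L]]
  stats::setNames(log2((tab$cond2 + pseudocount) /
                         (tab$cond1 + pseudocount)), ids)
}

#' Cumulative-fraction shift contrast between two groups
#'
#' Convenience wrapper bundling the two ECDFs, the Mann-Whitney test and
#' the median shift (median of group A minus median of group B; positive
#' means A is right-shifted).
#'
#' @param values_a,values_b numeric vectors for the two groups.
#' @param label_a,label_b group labels carried into the output.
#' @return list with `test` ([mann_whitney_u()] result), `ecdf_a`,
#'   `ecdf_b`, `median_shift` and the labels.
#' @export
cumulative_shift <- function(values_a, values_b,
                             label_a = "A", label_b = "B") {
  list(label_a = label_a, label_b = label_b,
       test = mann_whitney_u(values_a, values_b),
       ecdf_a = ecdf_table(values_a), ecdf_b = ecdf_table(values_b),
       median_shift = stats::median(values_a) - stats::median(values_b))
}
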