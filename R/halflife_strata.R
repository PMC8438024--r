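#' Classify transcript half-lives into short / middle / long
#'
#' Bins: short for 0-4 h, middle for 4-12 h, long for > 12 h. The
#' printed bin edges overlap at 4 and 12 h; the boundary is assigned to
#' the lower bin (closed upper edges), so 4 h is short and 12 h is
#' middle. Total function on [0, Inf).
#'
#' @param hours numeric vector of half-lives in hours, >= 0, finite.
#' @return character vector in {"short", "middle", "long"}.
#' @export
classify_halflife <- function(hours) {
  if (any(!is.finite(hours)) || any(hours < 0)) {
    stop("half-lives must be finite and >= 0")
  }
  ifelse(hours <= 4, "short", ifelse(hours <= 12, "middle", "long"))
}

#' Half-life-stratified shift analysis
#'
#' Within each half-life category, compares the condition log2 ratios of
#' target transcripts against non-targets with the Mann-Whitney U test.
#' Categories with fewer than `min_n` transcripts in either group are
#' reported but skipped (p = NA) with a message.
#'
#' @param log_ratios named numeric vector of per-transcript condition
#'   log2 ratios (e.g. from [condition_log2_ratio()]).
#' @param targets,non_targets transcript id vectors.
#' @param halflife_hours named numeric vector of half-lives.
#' @param min_n minimum group size per category (default 10).
#' @return data.frame with one row per category: n_targets,
#'   n_non_targets, U, z, p, method, median_shift, skipped.
#' @export
stratified_shift <- function(log_ratios, targets, non_targets,
                             halflife_hours, min_n = 10L) {
  cats <- c("short", "middle", "long")
  annotated <- intersect(names(log_ratios), names(halflife_hours))
  category <- stats::setNames(classify_halflife(halflife_hours[annotated]),
                              annotated)
  rows <- lapply(cats, function(cat) {
    ids <- annotated[category == cat]
    a <- log_ratios[intersect(ids, targets)]
    b <- log_ratios[intersect(ids, non_targets)]
    if (length(a) < min_n || length(b) < min_n) {
      message("stratified_shift: category '", cat, "' skipped (",
              length(a), " targets, ", length(b), " non-targets, min_n = ",
              min_n, ")")
      return(data.frame(category = cat, n_targets = length(a),
                        n_non_targets = length(b), U = NA_real_,
                        z = NA_real_, p = NA_real_, method = "skipped",
                        median_shift = NA_real_, skipped = TRUE,
                        stringsAsFactors = FALSE))
    }
    tst <- mann_whitney_u(a, b)
    data.frame(category = cat, n_targets = tst$n1, n_non_targets = tst$n2,
               U = tst$U, z = tst$z, p = tst$p_two_sided,
               method = tst$method,
               median_shift = stats::median(a) - stats::median(b),
               skipped = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fit exponential decay curves and recover half-lives per group
#'
#' Abundances are normalised to 1 at t = 0; the model
#' `log(abundance) = -(ln 2 / t_half) * t` is fitted by least squares
#' through the origin in log space. A non-negative fitted slope is
#' reported as non-decaying (t_half = Inf).
#'
#' @param time_h numeric vector of time points (hours), >= 3 distinct.
#' @param abundance positive numeric vector, same length, relative to t=0.
#' @param group factor/character of group labels, same length.
#' @return data.frame with group, t_half_hours, n_points; attribute
#'   `t_half_ratio` holds first group / second group when two groups.
#' @export
decay_curve_summary <- function(time_h, abundance, group = "all") {
  stopifnot(length(time_h) == length(abundance))
  if (any(!is.finite(abundance)) || any(abundance <= 0)) {
    stop("abundances must be positive and finite")
  }
  group <- rep_len(as.character(group), length(time_h))
  rows <- lapply(unique(group), function(g) {
    t <- time_h[group == g]; a <- abundance[group == g]
    if (length(unique(t)) < 3L) stop("group '", g, "' has < 3 timepoints")
    slope <- sum(t * log(a)) / sum(t^2)    # least squares through origin
    t_half <- if (slope >= 0) Inf else -log(2) / slope
    data.frame(group = g, t_half_hours = t_half, n_points = length(t),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (nrow(out) == 2L) {
    attr(out, "t_half_ratio") <- out$t_half_hours[1L] / out$t_half_hours[2L]
  }
  out
}
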