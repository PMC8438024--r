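# Independent oracles used across the suite. These deliberately avoid the
# package's code paths: the scanner oracle tests complementarity base by
# base, and the rank-test oracle builds U from the pair-counting identity.

RNA4 <- c("A", "C", "G", "U")

rand_rna <- function(len) paste(sample(RNA4, len, replace = TRUE),
                                collapse = "")

rna_comp <- c(A = "U", C = "G", G = "C", U = "A")

# does the UTR window starting at `pos` form a site of `type`?  checked by
# explicit Watson-Crick pairing against miRNA positions, not by pattern
# strings: target position k of the window pairs with the complementary
# miRNA seed position, and the A-anchored types require a literal A.
brute_is_site <- function(utr, mirna, pos, type) {
  uc <- strsplit(utr, "")[[1]]
  mc <- strsplit(mirna, "")[[1]]
  L <- length(uc)
  pairs_with <- function(u_idx, m_idx) {
    u_idx <= L && rna_comp[[uc[u_idx]]] == mc[m_idx]
  }
  if (type == "8mer") {
    if (pos + 7 > L) return(FALSE)
    for (k in 0:6) if (!pairs_with(pos + k, 8 - k)) return(FALSE)
    return(uc[pos + 7] == "A")
  }
  if (type == "7mer-m8") {
    if (pos + 6 > L) return(FALSE)
    for (k in 0:6) if (!pairs_with(pos + k, 8 - k)) return(FALSE)
    return(TRUE)
  }
  if (type == "7mer-A1") {
    if (pos + 6 > L) return(FALSE)
    for (k in 0:5) if (!pairs_with(pos + k, 7 - k)) return(FALSE)
    return(uc[pos + 6] == "A")
  }
  if (type == "6mer") {
    if (pos + 5 > L) return(FALSE)
    for (k in 0:5) if (!pairs_with(pos + k, 7 - k)) return(FALSE)
    return(TRUE)
  }
  stop("unknown type")
}

# exhaustive window-by-window scanner with the same published policy:
# strongest type per locus, then greedy non-overlap in strength order
brute_scan <- function(utr, mirna) {
  type_len <- c("8mer" = 8L, "7mer-m8" = 7L, "7mer-A1" = 7L, "6mer" = 6L)
  cand <- list()
  for (type in names(type_len)) {
    for (pos in seq_len(nchar(utr))) {
      if (brute_is_site(utr, mirna, pos, type)) {
        cand[[length(cand) + 1L]] <- data.frame(
          site_type = type, start = pos,
          end = pos + type_len[[type]] - 1L, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(cand) == 0L) {
    return(data.frame(site_type = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  cand <- do.call(rbind, cand)
  strength <- match(cand$site_type, c("8mer", "7mer-m8", "7mer-A1", "6mer"))
  cand <- cand[order(strength, cand$start), , drop = FALSE]
  kept <- cand[0, ]
  for (i in seq_len(nrow(cand))) {
    row <- cand[i, ]
    if (nrow(kept) == 0L ||
        all(row$end < kept$start | row$start > kept$end)) {
      kept <- rbind(kept, row)
    }
  }
  kept <- kept[order(kept$start), , drop = FALSE]
  rownames(kept) <- NULL
  kept
}

# exact two-sided Mann-Whitney p by full enumeration, with U built from
# the pair-counting identity U = #{x_i > y_j} + 0.5 #{x_i == y_j}
enum_mwu_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  N <- n1 + n2
  gt <- outer(pooled, pooled, ">") + 0.5 * outer(pooled, pooled, "==")
  combos <- combn(N, n1)
  u_of <- function(idx) sum(gt[idx, -idx, drop = FALSE])
  U_all <- apply(combos, 2, u_of)
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * n2 / 2
  mean(abs(U_all - mu) >= abs(u_obs - mu) - 1e-9)
}

site_key <- function(d) paste(d$transcript_id, d$mirna_id, d$site_type,
                              d$start, d$end)

small_sim_config <- function(...) {
  simulation_config(n_transcripts = 120L, n_mirnas = 12L,
                    utr_len_range = c(60L, 150L),
                    n_cohort_samples = 40L, n_background_genes = 60L,
                    n_signature_genes = 15L, ...)
}
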