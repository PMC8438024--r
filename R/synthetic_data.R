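RNA_BASES <- c("A", "C", "G", "U")

base_probs <- function(gc_content) {
  c(A = (1 - gc_content) / 2, C = gc_content / 2,
    G = gc_content / 2, U = (1 - gc_content) / 2)
}

#' Ordinal site strength of a seed-site type
#'
#' 8mer = 3, 7mer (either flavour) = 2, 6mer = 1, none = 0. Only the
#' ordering is meaningful; it encodes that stress effects grow with
#' seed-pairing strength.
#'
#' @param site_type character vector of types (or "none").
#' @return integer strengths.
#' @export
site_strength <- function(site_type) {
  unname(c("8mer" = 3L, "7mer-m8" = 2L, "7mer-A1" = 2L,
           "6mer" = 1L, "none" = 0L)[site_type])
}

#' Simulation configuration with validated defaults
#'
#' Defines the generative model behind every synthetic input: UTRs with
#' implanted seed sites, two-condition miRNA counts, RIP enrichment and
#' FPKM under a stress-attenuation model, half-lives, and a cohort with
#' a hypoxia signature gradient. Under stress, target RIP enrichment is
#' attenuated by `delta_binding` and target abundance increased by
#' `gamma_abundance` log2 units per unit site strength; a fraction
#' `frac_mirna_reduced` of miRNAs is down `lfc_reduced` log2 units.
#'
#' @param n_transcripts,n_mirnas counts (>= 1; n_mirnas >= 2).
#' @param utr_len_range (min, max) UTR length in nt; min >= 10 so an
#'   8mer site plus one-base flanks always fits.
#' @param gc_content background GC fraction in [0, 1].
#' @param site_type_probs named probabilities over
#'   {8mer, 7mer-m8, 7mer-A1, 6mer, none}, summing to 1.
#' @param delta_binding log2 attenuation of target RIP enrichment under
#'   stress per unit site strength (>= 0).
#' @param gamma_abundance log2 increase of target FPKM under stress per
#'   unit site strength (>= 0).
#' @param frac_mirna_reduced fraction of miRNAs reduced under stress.
#' @param lfc_reduced log2 fold change of reduced miRNAs (negative).
#' @param noise_sd log2-scale Gaussian noise sd (>= 0).
#' @param halflife_lognormal_params c(mu, sigma) on log-hours.
#' @param n_cohort_samples cohort size.
#' @param signature_effect log2 increase of signature-gene expression
#'   per unit latent hypoxia (>= 0).
#' @param rng_seed integer seed; every simulator derives its stream from
#'   it (offsets: +0 transcriptome, +1 miRNA counts, +2 RIP/expression,
#'   +3 cohort).
#' @param rip_base_log2,rip_base_sd baseline log2 RIP enrichment level
#'   and spread.
#' @param rip_strength_gain baseline log2 enrichment gain per unit site
#'   strength (targets bind AGO2 more than non-targets at baseline).
#' @param fpkm_base_log2_mean,fpkm_base_log2_sd baseline log2 FPKM.
#' @param mirna_abundance_meanlog,mirna_abundance_sdlog log-normal
#'   baseline miRNA abundance.
#' @param n_signature_genes,n_background_genes cohort gene-set sizes.
#' @return validated config list of class "sim_config".
#' @export
simulation_config <- function(n_transcripts = 1000L,
                              n_mirnas = 50L,
                              utr_len_range = c(150L, 600L),
                              gc_content = 0.5,
                              site_type_probs = c("8mer" = 0.10,
                                                  "7mer-m8" = 0.10,
                                                  "7mer-A1" = 0.10,
                                                  "6mer" = 0.20,
                                                  "none" = 0.50),
                              delta_binding = 1,
                              gamma_abundance = 0.5,
                              frac_mirna_reduced = 0.3,
                              lfc_reduced = -2,
                              noise_sd = 0.5,
                              halflife_lognormal_params = c(mu = log(8),
                                                            sigma = 0.9),
                              n_cohort_samples = 200L,
                              signature_effect = 2,
                              rng_seed = 1L,
                              rip_base_log2 = 1,
                              rip_base_sd = 0.75,
                              rip_strength_gain = 0.5,
                              fpkm_base_log2_mean = 6,
                              fpkm_base_log2_sd = 1,
                              mirna_abundance_meanlog = log(500),
                              mirna_abundance_sdlog = 1.2,
                              n_signature_genes = 50L,
                              n_background_genes = 400L) {
  cfg <- as.list(environment())
  type_names <- c(SITE_TYPES, "none")
  if (!setequal(names(cfg$site_type_probs), type_names)) {
    stop("site_type_probs must be named over {",
         paste(type_names, collapse = ", "), "}")
  }
  cfg$site_type_probs <- cfg$site_type_probs[type_names]
  if (abs(sum(cfg$site_type_probs) - 1) > 1e-9) {
    stop("site_type_probs must sum to 1 (got ", sum(cfg$site_type_probs), ")")
  }
  if (any(cfg$site_type_probs < 0)) stop("site_type_probs must be >= 0")
  for (f in c("n_transcripts", "n_mirnas", "n_cohort_samples",
              "n_signature_genes", "n_background_genes")) {
    if (cfg[[f]] < 1L) stop(f, " must be >= 1")
    cfg[[f]] <- as.integer(cfg[[f]])
  }
  if (cfg$n_mirnas < 2L) stop("n_mirnas must be >= 2")
  if (length(cfg$utr_len_range) != 2L ||
      cfg$utr_len_range[1L] > cfg$utr_len_range[2L]) {
    stop("utr_len_range must be (min, max) with min <= max")
  }
  if (cfg$utr_len_range[1L] < 10L) {
    stop("utr_len_range minimum must be at least 10 nt so that an 8mer ",
         "site plus one-base flanks fits in every UTR")
  }
  cfg$utr_len_range <- as.integer(cfg$utr_len_range)
  if (cfg$gc_content < 0 || cfg$gc_content > 1) stop("gc_content in [0,1]")
  if (cfg$frac_mirna_reduced < 0 || cfg$frac_mirna_reduced > 1) {
    stop("frac_mirna_reduced in [0,1]")
  }
  for (f in c("delta_binding", "gamma_abundance", "noise_sd",
              "signature_effect")) {
    if (cfg[[f]] < 0) stop(f, " must be >= 0")
  }
  cfg$rng_seed <- as.integer(cfg$rng_seed)
  class(cfg) <- "sim_config"
  cfg
}

random_rna <- function(len, probs) {
  paste(sample(RNA_BASES, len, replace = TRUE, prob = probs), collapse = "")
}

# draw one base from `allowed`, GC-biased when possible (uniform fallback
# for degenerate gc_content where every allowed base has probability 0)
draw_base <- function(allowed, probs) {
  w <- probs[allowed]
  if (sum(w) <= 0) w <- rep(1, length(allowed))
  if (length(allowed) == 1L) return(allowed)
  sample(allowed, 1L, prob = w / sum(w))
}

# replacement bases at position p that complete no seed core in any
# window covering p; only those windows can change under the mutation,
# so a safe choice strictly reduces the number of core occurrences
safe_bases <- function(chars, p, bad, cores) {
  allowed <- setdiff(RNA_BASES, bad)
  L <- length(chars)
  lo <- max(1L, p - 5L)
  hi <- min(L - 5L, p)
  if (hi < lo) return(allowed)
  Filter(function(b) {
    tmp <- chars
    tmp[p] <- b
    s <- paste(tmp[lo:(hi + 5L)], collapse = "")
    wins <- stringi::stri_sub(s, from = seq_len(hi - lo + 1L), length = 6L)
    !any(wins %in% cores)
  }, allowed)
}

# canonical offset of the 6mer seed core inside a written site string
core_offset <- function(site_type) {
  if (site_type %in% c("8mer", "7mer-m8")) 2L else 1L
}

# forbidden bases at the two flank positions of an implanted site, so a
# weaker implanted type can never be upgraded by a chance flanking base
flank_forbidden <- function(site_type, m8_complement) {
  switch(site_type,
         "8mer"    = list(prev = character(), nxt = character()),
         "7mer-m8" = list(prev = character(), nxt = "A"),
         "7mer-A1" = list(prev = m8_complement, nxt = character()),
         "6mer"    = list(prev = m8_complement, nxt = "A"))
}

# positions (starts) of any 6-mer core occurrence in a char vector
find_core_hits <- function(chars, cores) {
  L <- length(chars)
  if (L < 6L) return(integer(0))
  s <- paste(chars, collapse = "")
  windows <- stringi::stri_sub(s, from = seq_len(L - 5L), length = 6L)
  which(windows %in% cores)
}

#' Generate the synthetic transcriptome with implanted seed sites
#'
#' UTR sequences are random at the configured GC content; each
#' transcript draws one site type from `site_type_probs` and, unless
#' "none", hosts exactly one implanted site for one randomly chosen
#' miRNA at a uniform interior position. Two constraints make the
#' ground truth exactly recoverable by [scan_all_sites()]: chance
#' occurrences of any simulated miRNA's 6-mer seed core in the
#' background are removed (mutate-and-rescan outside implanted
#' intervals), and flanking bases adjacent to an implant are constrained
#' so a weaker implanted type cannot be upgraded. Half-lives are drawn
#' log-normal. miRNA sequences are 22 nt with pairwise-distinct seed
#' cores; a fraction `frac_mirna_reduced` is labelled "reduced", the
#' rest "non_difference".
#'
#' @param cfg a [simulation_config()].
#' @param seed RNG seed (default `cfg$rng_seed`).
#' @return list with `transcripts` (data.frame: transcript_id,
#'   utr_length, halflife_hours), `utrs` and `mirnas` (named sequence
#'   vectors) and `truth` (sites data.frame, per-transcript `strength`,
#'   per-miRNA `mirna_class`).
#' @export
generate_transcriptome <- function(cfg, seed = cfg$rng_seed) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  probs <- base_probs(cfg$gc_content)

  # miRNAs with pairwise-distinct seed cores (positions 2-7)
  mirna_ids <- sprintf("mir_%03d", seq_len(cfg$n_mirnas))
  mirnas <- character(cfg$n_mirnas)
  seen_seed <- character(0)
  for (i in seq_len(cfg$n_mirnas)) {
    repeat {
      s <- random_rna(22L, rep(0.25, 4L))
      hex <- substr(s, 2L, 7L)
      if (!(hex %in% seen_seed)) break
    }
    mirnas[i] <- s
    seen_seed <- c(seen_seed, substr(s, 2L, 7L))
  }
  names(mirnas) <- mirna_ids
  cores <- rc_rna(substr(mirnas, 2L, 7L))          # UTR-side 6-mer cores
  m8c <- substr(vapply(mirnas, function(m) site_patterns(m)[["7mer-m8"]],
                       character(1)), 1L, 1L)      # complement of position 8
  n_reduced <- round(cfg$frac_mirna_reduced * cfg$n_mirnas)
  reduced_ids <- sample(mirna_ids, n_reduced)
  mirna_class <- stats::setNames(
    ifelse(mirna_ids %in% reduced_ids, "reduced", "non_difference"),
    mirna_ids)

  tx_ids <- sprintf("tx_%04d", seq_len(cfg$n_transcripts))
  utrs <- character(cfg$n_transcripts)
  site_rows <- vector("list", cfg$n_transcripts)
  strength <- stats::setNames(integer(cfg$n_transcripts), tx_ids)
  type_names <- names(cfg$site_type_probs)

  for (i in seq_len(cfg$n_transcripts)) {
    L <- sample(seq(cfg$utr_len_range[1L], cfg$utr_len_range[2L]), 1L)
    type <- sample(type_names, 1L, prob = cfg$site_type_probs)
    chars <- sample(RNA_BASES, L, replace = TRUE, prob = probs)
    implant <- NULL
    if (type != "none") {
      # pick a miRNA whose written site string carries no other core
      implant_mi <- NA_integer_
      for (mi in sample(cfg$n_mirnas)) {
        pat <- site_patterns(mirnas[[mi]])[[type]]
        off <- core_offset(type)
        wins <- stringi::stri_sub(pat, from = seq_len(nchar(pat) - 5L),
                                  length = 6L)
        clean <- all(!(wins %in% cores) |
                       (seq_along(wins) == off & wins == cores[mi]))
        if (clean) { implant_mi <- mi; break }
      }
      if (is.na(implant_mi)) {
        stop("no miRNA admits a clean ", type, " implant for ", tx_ids[i])
      }
      pat <- site_patterns(mirnas[[implant_mi]])[[type]]
      len <- nchar(pat)
      start <- sample(seq(2L, L - len), 1L)
      end <- start + len - 1L
      chars[start:end] <- strsplit(pat, "")[[1L]]
      forb <- flank_forbidden(type, m8c[[implant_mi]])
      for (fp in list(list(pos = start - 1L, bad = forb$prev),
                      list(pos = end + 1L, bad = forb$nxt))) {
        if (length(fp$bad) > 0L && chars[fp$pos] %in% fp$bad) {
          chars[fp$pos] <- draw_base(setdiff(RNA_BASES, fp$bad), probs)
        }
      }
      implant <- list(mi = implant_mi, type = type, start = start, end = end)
      strength[i] <- site_strength(type)
    }
    # scrub chance seed cores outside the implanted interval
    for (iter in seq_len(200L)) {
      hits <- find_core_hits(chars, cores)
      if (!is.null(implant)) {
        canonical <- implant$start + core_offset(implant$type) - 1L
        hits <- hits[hits != canonical]
      }
      if (length(hits) == 0L) break
      if (iter == 200L) stop("core scrubbing did not converge for ", tx_ids[i])
      for (q in hits) {
        span <- q:(q + 5L)
        if (!is.null(implant)) span <- setdiff(span, implant$start:implant$end)
        if (length(span) == 0L) next
        bad_at <- function(p) {
          bad <- chars[p]
          if (!is.null(implant)) {
            forb <- flank_forbidden(implant$type, m8c[[implant$mi]])
            if (p == implant$start - 1L) bad <- c(bad, forb$prev)
            if (p == implant$end + 1L) bad <- c(bad, forb$nxt)
          }
          bad
        }
        done <- FALSE
        for (p in span) {            # first position with a core-free option
          safe <- safe_bases(chars, p, bad_at(p), cores)
          if (length(safe) > 0L) {
            chars[p] <- draw_base(safe, probs)
            done <- TRUE
            break
          }
        }
        if (!done) {                 # no safe option anywhere: randomise
          p <- span[1L]
          chars[p] <- draw_base(setdiff(RNA_BASES, bad_at(p)), probs)
        }
      }
    }
    utrs[i] <- paste(chars, collapse = "")
    if (!is.null(implant)) {
      site_rows[[i]] <- data.frame(
        transcript_id = tx_ids[i],
        mirna_id = mirna_ids[implant$mi],
        site_type = implant$type,
        start = implant$start, end = implant$end,
        stringsAsFactors = FALSE)
    }
  }
  names(utrs) <- tx_ids
  sites <- do.call(rbind, site_rows[!vapply(site_rows, is.null, logical(1))])
  if (is.null(sites)) {
    sites <- data.frame(transcript_id = character(), mirna_id = character(),
                        site_type = character(), start = integer(),
                        end = integer(), stringsAsFactors = FALSE)
  }
  hl <- stats::rlnorm(cfg$n_transcripts,
                      meanlog = cfg$halflife_lognormal_params[[1L]],
                      sdlog = cfg$halflife_lognormal_params[[2L]])
  list(
    transcripts = data.frame(transcript_id = tx_ids,
                             utr_length = nchar(utrs),
                             halflife_hours = hl,
                             stringsAsFactors = FALSE),
    utrs = utrs,
    mirnas = mirnas,
    truth = list(sites = sites, strength = strength,
                 mirna_class = mirna_class)
  )
}

#' Simulate a two-condition miRNA raw count table
#'
#' Baseline expected counts are log-normal; under stress (condition 2)
#' the expected counts of "reduced" miRNAs are scaled by
#' `2^lfc_reduced`; all counts get multiplicative log2-Gaussian noise of
#' sd `noise_sd` and are rounded to integers.
#'
#' @param cfg a [simulation_config()].
#' @param truth ground truth from [generate_transcriptome()] (supplies
#'   the per-miRNA class labels).
#' @param seed RNG seed (default `cfg$rng_seed + 1`).
#' @return data.frame with mirna_id, cond1, cond2 raw counts.
#' @export
simulate_mirna_counts <- function(cfg, truth, seed = cfg$rng_seed + 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  ids <- names(truth$mirna_class)
  n <- length(ids)
  base <- stats::rlnorm(n, cfg$mirna_abundance_meanlog,
                        cfg$mirna_abundance_sdlog)
  reduced <- truth$mirna_class == "reduced"
  exp1 <- base
  exp2 <- base * 2^(cfg$lfc_reduced * reduced)
  c1 <- round(exp1 * 2^stats::rnorm(n, 0, cfg$noise_sd))
  c2 <- round(exp2 * 2^stats::rnorm(n, 0, cfg$noise_sd))
  data.frame(mirna_id = ids, cond1 = pmax(c1, 0), cond2 = pmax(c2, 0),
             stringsAsFactors = FALSE)
}

#' Simulate RIP enrichment and FPKM tables under the stress model
#'
#' Per transcript t with site strength s_t: log2 RIP enrichment is
#' `base_t + rip_strength_gain * s_t` in condition 1 and additionally
#' `- delta_binding * s_t` under stress; log2 FPKM is `base'_t` in
#' condition 1 and `base'_t + gamma_abundance * s_t` under stress; both
#' get N(0, noise_sd^2) noise. Non-targets (s_t = 0) are exchangeable
#' between conditions. Tables are emitted on the natural (2^x) scale.
#'
#' @param transcript_ids transcript ids.
#' @param strength named (or aligned) integer site strengths.
#' @param cfg a [simulation_config()].
#' @param seed RNG seed (default `cfg$rng_seed + 2`).
#' @return list with `rip` (transcript_id, cond1, cond2 fold enrichment)
#'   and `fpkm` (gene_id, cond1, cond2).
#' @export
simulate_rip_and_expression <- function(transcript_ids, strength, cfg,
                                        seed = cfg$rng_seed + 2L) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(names(strength))) {
    stopifnot(all(transcript_ids %in% names(strength)))
    strength <- strength[transcript_ids]
  }
  stopifnot(length(strength) == length(transcript_ids))
  set.seed(seed)
  n <- length(transcript_ids)
  s <- as.numeric(strength)
  rip_base <- stats::rnorm(n, cfg$rip_base_log2, cfg$rip_base_sd)
  r1 <- rip_base + cfg$rip_strength_gain * s + stats::rnorm(n, 0, cfg$noise_sd)
  r2 <- rip_base + cfg$rip_strength_gain * s - cfg$delta_binding * s +
    stats::rnorm(n, 0, cfg$noise_sd)
  fpkm_base <- stats::rnorm(n, cfg$fpkm_base_log2_mean, cfg$fpkm_base_log2_sd)
  e1 <- fpkm_base + stats::rnorm(n, 0, cfg$noise_sd)
  e2 <- fpkm_base + cfg$gamma_abundance * s + stats::rnorm(n, 0, cfg$noise_sd)
  list(
    rip = data.frame(transcript_id = transcript_ids,
                     cond1 = 2^r1, cond2 = 2^r2, stringsAsFactors = FALSE),
    fpkm = data.frame(gene_id = transcript_ids,
                      cond1 = 2^e1, cond2 = 2^e2, stringsAsFactors = FALSE)
  )
}

#' Simulate a multi-sample cohort with a hypoxia signature gradient
#'
#' Each sample s carries a latent hypoxia level h_s ~ Uniform(0, 1).
#' Expected log2 expression of signature genes increases by
#' `signature_effect * h_s`, of target genes by
#' `gamma_abundance * h_s`; background genes are flat. Gaussian
#' log2-scale noise of sd `noise_sd` everywhere.
#'
#' @param cfg a [simulation_config()].
#' @param signature_genes,target_genes non-empty gene id vectors (need
#'   not be disjoint from each other or the background).
#' @param background_genes flat genes; defaults to
#'   `cfg$n_background_genes` generated ids.
#' @param seed RNG seed (default `cfg$rng_seed + 3`).
#' @return list with `fpkm` (gene_id + one column per sample) and
#'   `hypoxia` (named true latent levels).
#' @export
simulate_cohort <- function(cfg, signature_genes, target_genes,
                            background_genes = NULL,
                            seed = cfg$rng_seed + 3L) {
  stopifnot(inherits(cfg, "sim_config"))
  if (length(signature_genes) == 0L || length(target_genes) == 0L) {
    stop("signature and target gene sets must be non-empty")
  }
  if (is.null(background_genes)) {
    background_genes <- sprintf("bg_%04d", seq_len(cfg$n_background_genes))
  }
  genes <- unique(c(signature_genes, target_genes, background_genes))
  set.seed(seed)
  n_s <- cfg$n_cohort_samples
  samples <- sprintf("sample_%03d", seq_len(n_s))
  h <- stats::runif(n_s)
  base <- stats::rnorm(length(genes), cfg$fpkm_base_log2_mean,
                       cfg$fpkm_base_log2_sd)
  eff <- outer(as.numeric(genes %in% signature_genes) * cfg$signature_effect +
                 as.numeric(genes %in% target_genes) * cfg$gamma_abundance, h)
  lg <- base + eff +
    matrix(stats::rnorm(length(genes) * n_s, 0, cfg$noise_sd),
           nrow = length(genes))
  fpkm <- data.frame(gene_id = genes, 2^lg, stringsAsFactors = FALSE)
  names(fpkm) <- c("gene_id", samples)
  list(fpkm = fpkm, hypoxia = stats::setNames(h, samples))
}

#' Run the whole generator and return the study bundle
#'
#' Composes [generate_transcriptome()], [simulate_mirna_counts()],
#' [simulate_rip_and_expression()] and [simulate_cohort()] with their
#' documented per-stage seeds, so the bundle is fully determined by the
#' config. Cohort target genes are the ground-truth exclusive targets
#' (transcripts whose implanted miRNA is non-difference); the hypoxia
#' signature gets its own generated gene ids.
#'
#' @param cfg a [simulation_config()].
#' @return list with cfg, transcripts, utrs, mirnas, truth,
#'   mirna_counts, rip, fpkm, signature_genes, cohort.
#' @export
simulate_study <- function(cfg) {
  tr <- generate_transcriptome(cfg)
  counts <- simulate_mirna_counts(cfg, tr$truth)
  ripex <- simulate_rip_and_expression(tr$transcripts$transcript_id,
                                       tr$truth$strength, cfg)
  signature_genes <- sprintf("hyp_sig_%03d", seq_len(cfg$n_signature_genes))
  nd_mirnas <- names(tr$truth$mirna_class)[tr$truth$mirna_class ==
                                             "non_difference"]
  target_genes <- unique(
    tr$truth$sites$transcript_id[tr$truth$sites$mirna_id %in% nd_mirnas])
  if (length(target_genes) == 0L) target_genes <- "placeholder_target"
  background_genes <- setdiff(tr$transcripts$transcript_id, target_genes)
  cohort <- simulate_cohort(cfg, signature_genes, target_genes,
                            background_genes)
  list(cfg = cfg, transcripts = tr$transcripts, utrs = tr$utrs,
       mirnas = tr$mirnas, truth = tr$truth, mirna_counts = counts,
       rip = ripex$rip, fpkm = ripex$fpkm,
       signature_genes = signature_genes, cohort = cohort)
}

#' Write a simulated study bundle to disk in the pipeline's formats
#'
#' Emits `utrs.fasta`, `mirnas.fasta`, `rip_enrichment.tsv`, `fpkm.tsv`,
#' `mirna_counts.tsv`, `halflife.tsv`, `signature.txt`,
#' `cohort_fpkm.tsv`, `true_hypoxia.tsv` and `ground_truth.tsv`.
#'
#' @param study output of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_fasta(study$utrs, p("utrs.fasta"))
  write_fasta(study$mirnas, p("mirnas.fasta"))
  write_tsv(study$rip, p("rip_enrichment.tsv"))
  write_tsv(study$fpkm, p("fpkm.tsv"))
  write_tsv(study$mirna_counts, p("mirna_counts.tsv"))
  write_tsv(study$transcripts[, c("transcript_id", "halflife_hours")],
            p("halflife.tsv"))
  writeLines(study$signature_genes, p("signature.txt"))
  write_tsv(study$cohort$fpkm, p("cohort_fpkm.tsv"))
  write_tsv(data.frame(sample_id = names(study$cohort$hypoxia),
                       true_hypoxia = unname(study$cohort$hypoxia)),
            p("true_hypoxia.tsv"))
  gt <- study$truth$sites
  gt$strength <- site_strength(gt$site_type)
  gt$mirna_class <- unname(study$truth$mirna_class[gt$mirna_id])
  write_tsv(gt, p("ground_truth.tsv"))
  invisible(dir)
}
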