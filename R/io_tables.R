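#' Read a FASTA file into a named vector of RNA sequences
#'
#' Record ids are the first whitespace-delimited token of each header.
#' Sequences are normalised to the internal RNA alphabet (upper case,
#' T unified to U).
#'
#' @param path path to a FASTA file.
#' @return named character vector, id -> RNA sequence.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "[ \t]"), `[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate FASTA id: ", paste(unique(dup), collapse = ", "))
  }
  seqs <- as.character(set)
  names(seqs) <- ids
  for (i in seq_along(seqs)) {
    seqs[[i]] <- normalize_rna(seqs[[i]], what = paste0("record '", ids[[i]], "'"))
  }
  seqs
}

#' Write sequences as FASTA wrapped at 60 columns
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), !anyNA(names(seqs)))
  set <- Biostrings::BStringSet(unname(as.character(seqs)))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

# shared strict reader for headed TSV tables; numeric_cols are validated
# cell-by-cell so errors can cite the offending line of the file
read_tsv_strict <- function(path, numeric_cols, nonneg_cols = character(),
                            positive_cols = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  if (nrow(tab) == 0L) stop("no data rows in ", path)
  for (col in numeric_cols) {
    if (!col %in% names(tab)) stop("missing column '", col, "' in ", path)
    vals <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(!is.finite(vals))
    if (length(bad) > 0L) {
      stop("non-finite or unparseable value in column '", col, "' of ",
           path, " at line ", bad[1L] + 1L)  # +1 for the header row
    }
    if (col %in% nonneg_cols && any(vals < 0)) {
      stop("negative value in column '", col, "' of ", path,
           " at line ", which(vals < 0)[1L] + 1L)
    }
    if (col %in% positive_cols && any(vals <= 0)) {
      stop("non-positive value in column '", col, "' of ", path,
           " at line ", which(vals <= 0)[1L] + 1L)
    }
    tab[[col]] <- vals
  }
  tab
}

check_unique_ids <- function(ids, path) {
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate id in ", path, ": ", paste(unique(dup), collapse = ", "))
  }
}

#' Read a gene expression matrix (FPKM) from TSV
#'
#' First column is the gene id; every remaining column is one sample of
#' non-negative finite FPKM values.
#'
#' @param path path to a TSV file with a header row.
#' @return data.frame with column `gene_id` followed by numeric sample columns.
#' @export
read_expression_tsv <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L) stop("expression table needs >= 1 sample column: ", path)
  tab <- read_tsv_strict(path, numeric_cols = header[-1L],
                         nonneg_cols = header[-1L])
  names(tab)[1L] <- "gene_id"
  check_unique_ids(tab$gene_id, path)
  tab
}

#' Read a per-transcript RIP fold-enrichment table from TSV
#'
#' Columns: `transcript_id`, `cond1`, `cond2`; enrichment values must be
#' strictly positive so they are log-transformable.
#'
#' @param path path to a TSV file.
#' @return data.frame with transcript_id and positive numeric conditions.
#' @export
read_rip_tsv <- function(path) {
  tab <- read_tsv_strict(path, numeric_cols = c("cond1", "cond2"),
                         positive_cols = c("cond1", "cond2"))
  names(tab)[1L] <- "transcript_id"
  check_unique_ids(tab$transcript_id, path)
  tab[, c("transcript_id", "cond1", "cond2")]
}

#' Read a two-condition miRNA raw count table from TSV
#'
#' @param path path to a TSV with columns `mirna_id`, `cond1`, `cond2`.
#' @return data.frame of non-negative counts.
#' @export
read_mirna_counts <- function(path) {
  tab <- read_tsv_strict(path, numeric_cols = c("cond1", "cond2"),
                         nonneg_cols = c("cond1", "cond2"))
  names(tab)[1L] <- "mirna_id"
  check_unique_ids(tab$mirna_id, path)
  tab[, c("mirna_id", "cond1", "cond2")]
}

#' Read a transcript half-life table (hours) from TSV
#'
#' A half-life of exactly 0 h is accepted (it classifies as short).
#'
#' @param path path to a TSV with columns `transcript_id`, `halflife_hours`.
#' @return named numeric vector, transcript id -> half-life in hours.
#' @export
read_halflife <- function(path) {
  tab <- read_tsv_strict(path, numeric_cols = "halflife_hours",
                         nonneg_cols = "halflife_hours")
  names(tab)[1L] <- "transcript_id"
  check_unique_ids(tab$transcript_id, path)
  stats::setNames(tab$halflife_hours, tab$transcript_id)
}

#' Read a gene signature list (one id per line, '#' comments allowed)
#'
#' @param path path to a plain-text file.
#' @return character vector of gene ids.
#' @export
read_signature <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("no gene ids in signature file: ", path)
  lines
}

#' Write a table as TSV (full precision, '.' decimal, no quoting)
#'
#' Numeric columns are serialised with 15 significant digits so that a
#' write/read round trip reproduces values exactly at double precision.
#'
#' @param tab data.frame to write.
#' @param path output path.
#' @export
write_tsv <- function(tab, path) {
  out <- tab
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      out[[col]] <- formatC(out[[col]], digits = 15, format = "g")
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
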