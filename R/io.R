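#' Read a feature-by-sample count table
#'
#' Reads a tab-delimited table whose first column holds feature identifiers
#' (contigs, MAGs, KOs or pathways) and whose remaining columns hold
#' nonnegative numeric counts, one column per sample. Missing cells and
#' negative values are errors, not implicit zeros: silent zero-filling
#' masks join bugs between the count matrix and its annotation tables.
#'
#' @param path Path to a TSV file (UTF-8, header row).
#' @return A numeric matrix with feature row names and sample column names.
#' @export
read_count_table <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  hdr <- colnames(df)
  check_no_duplicates(hdr, "column header")
  check_no_duplicates(as.character(df[[1L]]), "row label")
  m <- as_count_matrix(df, arg = basename(path))
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)
    abort(sprintf("missing value at row '%s', column '%s'",
                  rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
  }
  check_nonnegative(m)
  m
}

#' Write a count table as TSV
#'
#' Inverse of [read_count_table()]; round-trips bit-identically for valid
#' integer-valued matrices.
#'
#' @param x Matrix with row and column names.
#' @param path Output path.
#' @param id_column Name for the first (feature id) column.
#' @export
write_count_table <- function(x, path, id_column = "feature_id") {
  x <- as_count_matrix(x)
  df <- data.frame(id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genome sequences from FASTA
#'
#' Parses a FASTA file into a named character vector of uppercase
#' nucleotide sequences. Sequences are matched case-insensitively;
#' non-ACGT IUPAC symbols are retained but flagged in the
#' `"ambiguous"` attribute (a named logical, one entry per record).
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences, with attribute
#'   `"ambiguous"` marking records containing non-ACGT symbols.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  check_no_duplicates(ids, "FASTA record id")
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  if (any(nchar(seqs) == 0)) {
    abort(sprintf("empty FASTA record: %s",
                  paste(ids[nchar(seqs) == 0], collapse = ", ")))
  }
  attr(seqs, "ambiguous") <- setNames(grepl("[^ACGT]", seqs), ids)
  seqs
}

#' Write sequences to FASTA
#'
#' @param sequences Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @export
write_fasta <- function(sequences, path, width = 70) {
  set <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Validate and normalise sample metadata
#'
#' Sample metadata describes the crossover feeding trial: each sample is
#' one animal in one period on one diet (percent of maintenance energy
#' requirement, MER). Identifiers must be unique and no animal can appear
#' twice in the same period.
#'
#' @param df Data frame with columns `sample_id`, `animal_id`, `period`
#'   (integer 1-4) and `diet` (one of 40, 60, 80, 100).
#' @return A validated tibble.
#' @export
as_sample_metadata <- function(df) {
  need <- c("sample_id", "animal_id", "period", "diet")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0) {
    abort(sprintf("metadata missing columns: %s", paste(miss, collapse = ", ")))
  }
  out <- as_tibble(df)
  out$sample_id <- as.character(out$sample_id)
  out$animal_id <- as.character(out$animal_id)
  out$period <- as.integer(out$period)
  out$diet <- as.integer(out$diet)
  check_no_duplicates(out$sample_id, "sample_id")
  if (!all(out$period %in% 1:4)) abort("period must be in 1..4")
  if (!all(out$diet %in% c(40L, 60L, 80L, 100L))) {
    abort("diet must be one of 40, 60, 80, 100 (% MER)")
  }
  check_no_duplicates(paste(out$animal_id, out$period), "(animal, period) pair")
  out
}

#' Read sample metadata from TSV
#'
#' @param path Path to a TSV with columns `sample_id`, `animal_id`,
#'   `period`, `diet`.
#' @return A validated metadata tibble (see [as_sample_metadata()]).
#' @export
read_sample_metadata <- function(path) {
  as_sample_metadata(read.delim(path, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE))
}

#' Read a genome taxonomy table
#'
#' One row per genome with ordered rank labels from domain down to genus.
#' Ranks that could not be resolved carry the sentinel `"unclassified"`.
#'
#' @param path Path to a TSV with a `genome_id` column and rank columns.
#' @return A tibble with unique `genome_id`.
#' @export
read_taxonomy <- function(path) {
  df <- as_tibble(read.delim(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE))
  if (!"genome_id" %in% colnames(df)) abort("taxonomy needs a genome_id column")
  df$genome_id <- as.character(df$genome_id)
  check_no_duplicates(df$genome_id, "genome_id")
  df
}

#' Read a KO-to-pathway map
#'
#' @param path Path to a TSV with columns `ko` and `pathway`; a KO may map
#'   to several pathways (one row each).
#' @return A tibble with columns `ko` and `pathway`.
#' @export
read_pathway_map <- function(path) {
  df <- as_tibble(read.delim(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE))
  if (!all(c("ko", "pathway") %in% colnames(df))) {
    abort("pathway map needs columns ko, pathway")
  }
  df
}

#' Drop excluded periods and diets from the sample set
#'
#' Period-1 samples were frozen without cryoprotectant (a storage batch
#' confounder) and the 100% MER ration contained additional cottonseed
#' and molasses (a compositional confounder), so both are excluded from
#' diet comparisons by default. With the bundled crossover design this
#' leaves 14 samples in a 4:5:5 split across the 40:60:80 %MER groups.
#'
#' @param metadata Sample metadata (see [as_sample_metadata()]).
#' @param exclude_periods Periods to drop (default 1).
#' @param exclude_diets Diets to drop (default 100).
#' @return The retained metadata tibble. Idempotent.
#' @export
filter_samples <- function(metadata, exclude_periods = 1L,
                           exclude_diets = 100L) {
  metadata <- as_sample_metadata(metadata)
  out <- metadata[!(metadata$period %in% exclude_periods) &
                    !(metadata$diet %in% exclude_diets), , drop = FALSE]
  if (nrow(out) == 0) abort("no samples left after filtering")
  out
}
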