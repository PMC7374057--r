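#' Read coding sequences from FASTA
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] returning a named
#' character vector, the sequence container used throughout the package.
#'
#' @param path FASTA file (multi-record, wrapped lines allowed).
#' @return Named character vector of uppercase DNA sequences.
#' @export
read_cds_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a tRNA gene copy number table
#'
#' GtRNAdb-style export: a TSV with columns `anticodon` (5'->3' triplets)
#' and `copy_number`.
#'
#' @param path TSV file.
#' @return Named numeric vector anticodon -> copies.
#' @export
read_trna_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("anticodon", "copy_number") %in% names(df))) {
    stop("tRNA table needs columns 'anticodon' and 'copy_number'")
  }
  stats::setNames(df$copy_number, normalize_dna(df$anticodon))
}

#' Read a protein abundance table
#'
#' PaxDB-style export: a TSV with columns `protein` and `abundance`.
#'
#' @param path TSV file.
#' @return Named numeric vector protein -> abundance.
#' @export
read_abundance_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("protein", "abundance") %in% names(df))) {
    stop("abundance table needs columns 'protein' and 'abundance'")
  }
  stats::setNames(df$abundance, df$protein)
}

#' Read a gene-set partition table
#'
#' TSV with columns `gene` and `set` assigning each gene to singletons,
#' C1..Cn, or PHE.
#'
#' @param path TSV file.
#' @return Data frame with columns `gene`, `set`.
#' @export
read_partition_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "set") %in% names(df))) {
    stop("partition table needs columns 'gene' and 'set'")
  }
  df[, c("gene", "set")]
}

#' Write a codon count table or matrix as TSV
#'
#' Genes in rows, the 61 sense codons as a header row in fixed
#' alphabetical order.
#'
#' @param x Matrix (e.g. `codon_counts`, coordinates, distances).
#' @param path Output file.
#' @param rowname_header Name for the row-name column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(x, path, rowname_header = "gene") {
  df <- data.frame(rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- rowname_header
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a usage profile as TSV
#'
#' Columns `codon`, `cuf`, `rscu` (NA for absent families).
#'
#' @param profile A [usage_profile()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  df <- data.frame(codon = names(profile$cuf), cuf = profile$cuf,
                   rscu = profile$rscu, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
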