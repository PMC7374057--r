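#' Count codons in coding sequences
#'
#' Produces the raw codon count (RCC) table used as input to every usage
#' statistic and to the correspondence analysis: one row per gene, one
#' column per sense codon. Stop codons are never counted; codons containing
#' a non-ACGT character are skipped and tallied per gene.
#'
#' @param seqs Named character vector of nucleotide sequences (or a
#'   `Biostrings::DNAStringSet`). U is accepted and converted to T.
#' @param code A [genetic_code()].
#' @param frame Frame policy. `"strict"` (default) errors on a sequence
#'   whose length is not divisible by 3, naming the gene; `"trim"` drops the
#'   trailing partial codon with a warning.
#'
#' @return An integer matrix of class `codon_counts`, genes x 61 sense
#'   codons (columns in fixed alphabetical order), with attributes
#'   `skipped` (ambiguous codons dropped per gene) and `code_table`.
#'   Empty input gives a 0-row table.
#'
#' @examples
#' counts <- count_codons(c(g1 = "ATGAAATAA", g2 = "ATGAANGGG"))
#' rowSums(counts)
#' @export
count_codons <- function(seqs, code = genetic_code(),
                         frame = c("strict", "trim")) {
  frame <- match.arg(frame)
  if (inherits(seqs, "DNAStringSet")) {
    seqs <- as.character(seqs)
  }
  if (is.null(names(seqs)) && length(seqs) > 0) {
    names(seqs) <- paste0("gene", seq_along(seqs))
  }
  mat <- matrix(0L, nrow = length(seqs), ncol = length(code$codons),
                dimnames = list(names(seqs), code$codons))
  skipped <- integer(length(seqs))
  names(skipped) <- names(seqs)
  for (i in seq_along(seqs)) {
    s <- normalize_dna(seqs[[i]])
    n <- nchar(s)
    if (n %% 3L != 0L) {
      if (frame == "strict") {
        stop("sequence length of '", names(seqs)[i],
             "' (", n, " nt) is not divisible by 3")
      }
      warning("trimming partial trailing codon of '", names(seqs)[i], "'")
      n <- n - n %% 3L
      s <- substr(s, 1L, n)
    }
    if (n == 0L) next
    cods <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
    ok <- cods %in% names(code$codon_to_aa)
    skipped[i] <- sum(!ok)
    cods <- cods[ok]
    cods <- cods[!cods %in% code$stops]
    if (length(cods)) {
      tab <- table(factor(cods, levels = code$codons))
      mat[i, ] <- as.integer(tab)
    }
  }
  structure(mat, skipped = skipped, code_table = code$table_id,
            class = c("codon_counts", class(mat)))
}

#' Aggregate codon counts over a gene set
#'
#' Element-wise sum of the rows of a codon-count table, optionally
#' restricted to a subset of genes.
#'
#' @param counts A `codon_counts` matrix (or any genes x codons matrix).
#' @param genes Optional character vector of row names to pool.
#' @return Named numeric vector of pooled counts over the 61 sense codons.
#' @export
pool_counts <- function(counts, genes = NULL) {
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(counts))
    if (length(missing)) {
      stop("genes absent from count table: ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
    counts <- counts[genes, , drop = FALSE]
  }
  colSums(counts)
}

# coerce a counts argument (vector, 1-row matrix, or matrix to be pooled)
# into a named numeric vector over the code's sense codons
as_count_vector <- function(counts, code) {
  if (is.matrix(counts)) {
    counts <- colSums(counts)
  }
  if (is.null(names(counts))) {
    if (length(counts) != length(code$codons)) {
      stop("unnamed counts must have length ", length(code$codons))
    }
    names(counts) <- code$codons
  }
  out <- stats::setNames(numeric(length(code$codons)), code$codons)
  shared <- intersect(names(counts), code$codons)
  out[shared] <- counts[shared]
  out
}
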