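#' Genetic code tables
#'
#' Builds the genetic code used throughout the package: the mapping from the
#' 64 triplets to amino acids, the synonymous families, and the degeneracy
#' census. The default is NCBI translation table 11 (bacterial, archaeal and
#' plant plastid code), whose codon-to-amino-acid map coincides with the
#' standard code; alternative start codons are not special-cased, so every
#' codon is counted with its sense meaning.
#'
#' @param table_id Integer code-table identifier. Currently tables 1 and 11
#'   (identical codon maps) are supported.
#'
#' @return An object of class `genetic_code`: a list with elements
#'   `table_id`, `codon_to_aa` (named character over all 64 triplets, stops
#'   as `"*"`), `codons` (the 61 sense codons, alphabetical), `stops`,
#'   `families` (named list, amino acid -> synonymous codons), and
#'   `degeneracy` (named integer, amino acid -> family size).
#'
#' @examples
#' code <- genetic_code()
#' code$families[["K"]]        # the lysine family: AAA, AAG
#' table(code$degeneracy)      # degeneracy census of the standard code
#' @export
genetic_code <- function(table_id = 11L) {
  if (!table_id %in% c(1L, 11L)) {
    stop("unsupported translation table: ", table_id)
  }
  bases <- c("T", "C", "A", "G")
  triplets <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  # standard code in TCAG order: aa string indexed as first base slowest
  aa <- character(64)
  names(aa) <- triplets
  aa_str <- "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"
  # aa_str is laid out first-base T,C,A,G (blocks of 16), second base T,C,A,G
  # (blocks of 4), third base T,C,A,G -- build index accordingly
  idx <- 1L
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    aa[paste0(b1, b2, b3)] <- substr(aa_str, idx, idx)
    idx <- idx + 1L
  }
  sense <- sort(names(aa)[aa != "*"])
  stops <- sort(names(aa)[aa == "*"])
  fams <- split(sense, aa[sense])
  fams <- lapply(fams, sort)
  degeneracy <- vapply(fams, length, integer(1))
  structure(
    list(
      table_id = table_id,
      codon_to_aa = aa,
      codons = sense,
      stops = stops,
      families = fams,
      degeneracy = degeneracy
    ),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code (translation table ", x$table_id, ")\n", sep = "")
  cat(" ", length(x$codons), "sense codons,", length(x$stops), "stops\n")
  cat("  degeneracy census:",
      paste(sprintf("%d-fold x%d", as.integer(names(table(x$degeneracy))),
                    as.integer(table(x$degeneracy))), collapse = ", "), "\n")
  invisible(x)
}

# amino acid of each codon (vectorized); codons assumed valid triplets
codon_aa <- function(code, codons) {
  unname(code$codon_to_aa[codons])
}

#' Translate coding sequences
#'
#' Translates in-frame nucleotide sequences to protein using the package's
#' genetic code table. Stops translate to `"*"`; a single terminal stop is
#' kept so callers can strip or check it.
#'
#' @param seqs Character vector of in-frame DNA sequences (U is accepted and
#'   converted to T).
#' @param code A [genetic_code()].
#' @return Character vector of amino-acid sequences.
#' @export
translate_cds <- function(seqs, code = genetic_code()) {
  vapply(seqs, function(s) {
    s <- normalize_dna(s)
    if (nchar(s) %% 3L != 0L) stop("sequence length not divisible by 3")
    cods <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
    paste(ifelse(cods %in% names(code$codon_to_aa),
                 code$codon_to_aa[cods], "X"), collapse = "")
  }, character(1), USE.NAMES = !is.null(names(seqs)))
}

# uppercase, RNA -> DNA
normalize_dna <- function(s) {
  chartr("u", "T", chartr("U", "T", toupper(s)))
}

# reverse complement of a triplet (or any string)
revcomp <- function(s) {
  comp <- chartr("ACGT", "TGCA", s)
  vapply(strsplit(comp, ""), function(x) paste(rev(x), collapse = ""),
         character(1))
}

# largest-remainder rounding of non-negative weights to integers summing to
# `total`; ties broken by position order
largest_remainder <- function(w, total) {
  stopifnot(all(w >= 0), total >= 0)
  if (sum(w) == 0) {
    out <- integer(length(w))
    names(out) <- names(w)
    return(out)
  }
  x <- w / sum(w) * total
  fl <- floor(x)
  rem <- total - sum(fl)
  if (rem > 0) {
    ord <- order(x - fl, decreasing = TRUE)
    fl[ord[seq_len(rem)]] <- fl[ord[seq_len(rem)]] + 1
  }
  out <- as.integer(fl)
  names(out) <- names(w)
  out
}

# run `expr` with a local RNG state seeded by `seed`, restoring the caller's
# stream afterwards
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
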