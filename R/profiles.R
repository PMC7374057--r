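#' Codon usage profile of a gene or gene set
#'
#' Computes, from a (pooled) codon-count vector, the codon usage frequencies
#' (CUF: each codon's share within its synonymous family), the relative
#' synonymous codon usage (RSCU = family size x CUF), the amino-acid
#' composition, and GC3 (fraction of G or C at the third codon position
#' among sense codons). Families with zero counts are left undefined (NA),
#' not zero-filled; [rscu_matrix()] applies the zero-fill convention used
#' for correspondence-analysis input.
#'
#' @param counts Named numeric vector of codon counts (or a `codon_counts`
#'   matrix, which is pooled over rows).
#' @param code A [genetic_code()].
#'
#' @return Object of class `usage_profile`: list with `cuf`, `rscu` (named
#'   over the 61 sense codons, NA for absent families), `aa_freq` (sums to
#'   1 over amino acids present), `gc3`, `n_codons`, and `code_table`.
#'
#' @examples
#' p <- usage_profile(c(AAA = 3, AAG = 1))
#' p$cuf[c("AAA", "AAG")]   # 0.75, 0.25
#' @export
usage_profile <- function(counts, code = genetic_code()) {
  x <- as_count_vector(counts, code)
  total <- sum(x)
  if (total <= 0) stop("no sense codons in input counts")
  aa <- codon_aa(code, code$codons)
  fam_tot <- tapply(x, aa, sum)
  cuf <- x / as.numeric(fam_tot[aa])
  cuf[fam_tot[aa] == 0] <- NA_real_
  k <- code$degeneracy[aa]
  rscu <- as.numeric(k) * cuf
  aa_freq <- as.numeric(fam_tot) / total
  names(aa_freq) <- names(fam_tot)
  third <- substr(code$codons, 3, 3)
  gc3 <- sum(x[third %in% c("G", "C")]) / total
  structure(
    list(cuf = cuf, rscu = rscu, aa_freq = aa_freq, gc3 = gc3,
         n_codons = total, code_table = code$table_id),
    class = "usage_profile"
  )
}

#' @export
print.usage_profile <- function(x, ...) {
  cat("Codon usage profile:", x$n_codons, "sense codons, GC3 =",
      format(round(x$gc3, 4)), "\n")
  nund <- sum(is.na(x$cuf))
  if (nund) cat(" ", nund, "codons in absent families (CUF undefined)\n")
  invisible(x)
}

#' Construct a usage profile from explicit CUF values
#'
#' Builds a `usage_profile` directly from per-codon within-family
#' frequencies and an amino-acid composition, e.g. to specify a target
#' profile for the synthetic-data generator or to score a hypothetical
#' usage with [modal_tai()].
#'
#' @param cuf Named numeric vector over (a subset of) the 61 sense codons;
#'   within every supplied family the values must sum to 1.
#' @param aa_freq Named numeric vector of amino-acid frequencies (single
#'   letters); will be renormalized to sum to 1.
#' @param code A [genetic_code()].
#' @return A `usage_profile` whose `gc3` is the expected GC3 under `cuf`
#'   and `aa_freq`.
#' @export
profile_from_cuf <- function(cuf, aa_freq, code = genetic_code()) {
  full <- stats::setNames(rep(NA_real_, length(code$codons)), code$codons)
  bad <- setdiff(names(cuf), code$codons)
  if (length(bad)) stop("unknown codons: ", paste(bad, collapse = ", "))
  full[names(cuf)] <- cuf
  aa <- codon_aa(code, code$codons)
  for (a in unique(aa[!is.na(full)])) {
    s <- sum(full[aa == a], na.rm = TRUE)
    if (abs(s - 1) > 1e-8) {
      stop("cuf for family ", a, " sums to ", format(s), ", not 1")
    }
  }
  af <- stats::setNames(rep(0, length(code$families)), names(code$families))
  af[names(aa_freq)] <- aa_freq
  af <- af / sum(af)
  pos <- af[aa] * full
  third <- substr(code$codons, 3, 3)
  gc3 <- sum(pos[third %in% c("G", "C")], na.rm = TRUE) / sum(pos, na.rm = TRUE)
  k <- code$degeneracy[aa]
  structure(
    list(cuf = full, rscu = as.numeric(k) * full, aa_freq = af, gc3 = gc3,
         n_codons = NA_real_, code_table = code$table_id),
    class = "usage_profile"
  )
}

#' RSCU matrix for correspondence-analysis input
#'
#' Per-gene RSCU values with the CA-input convention: codons of families
#' absent from a gene contribute 0 (instead of NA) so that the matrix is
#' non-negative and complete.
#'
#' @param counts A `codon_counts` matrix.
#' @param code A [genetic_code()].
#' @return Numeric matrix, genes x 61 codons.
#' @export
rscu_matrix <- function(counts, code = genetic_code()) {
  aa <- codon_aa(code, code$codons)
  k <- as.numeric(code$degeneracy[aa])
  out <- matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  for (i in seq_len(nrow(counts))) {
    x <- counts[i, ]
    fam_tot <- tapply(x, aa, sum)
    denom <- as.numeric(fam_tot[aa])
    v <- ifelse(denom > 0, k * x / denom, 0)
    out[i, ] <- v
  }
  out
}

#' GC content helpers
#'
#' `gc_content()` is the overall G+C fraction of the counted codons (all
#' three positions); `gc3_content()` is the third-position fraction only.
#' Both operate on a (pooled) codon-count vector.
#'
#' @param counts Codon counts (vector or matrix, pooled).
#' @param code A [genetic_code()].
#' @return A fraction in [0, 1].
#' @export
gc_content <- function(counts, code = genetic_code()) {
  x <- as_count_vector(counts, code)
  total <- 3 * sum(x)
  if (total == 0) return(NA_real_)
  gc <- vapply(code$codons, function(cod) {
    sum(strsplit(cod, "")[[1]] %in% c("G", "C"))
  }, numeric(1))
  sum(gc * x) / total
}

#' @rdname gc_content
#' @export
gc3_content <- function(counts, code = genetic_code()) {
  x <- as_count_vector(counts, code)
  if (sum(x) == 0) return(NA_real_)
  third <- substr(code$codons, 3, 3)
  sum(x[third %in% c("G", "C")]) / sum(x)
}

#' Wright's effective number of codons (Nc)
#'
#' Computes Nc from a (pooled) codon-count vector: per amino acid the
#' homozygosity F = (n * sum(p_i^2) - 1) / (n - 1) for n > 1 counted
#' codons, averaged within each degeneracy class, then
#' Nc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6 for the standard code. Nc runs from
#' 20 (one codon per amino acid) to 61 (uniform synonymous usage, large
#' counts). A missing three-fold class mean (no usable Ile counts) is
#' imputed as the harmonic mean of the two- and four-fold class means;
#' families with n <= 1 are omitted from their class mean. Values above 61
#' can occur for very small genes and are reported as-is with a warning.
#'
#' @param counts Codon counts (vector or matrix, pooled).
#' @param code A [genetic_code()].
#' @return Nc as a single numeric value, or NA (with a warning) when no
#'   class mean is computable.
#' @export
effective_number_of_codons <- function(counts, code = genetic_code()) {
  x <- as_count_vector(counts, code)
  aa <- codon_aa(code, code$codons)
  k_of_aa <- code$degeneracy
  f_hat <- stats::setNames(rep(NA_real_, length(k_of_aa)), names(k_of_aa))
  for (a in names(k_of_aa)) {
    if (k_of_aa[[a]] < 2) next
    n_a <- sum(x[aa == a])
    if (n_a < 2) next
    p <- x[aa == a] / n_a
    f_hat[a] <- (n_a * sum(p^2) - 1) / (n_a - 1)
  }
  class_mean <- function(k) {
    vals <- f_hat[names(k_of_aa)[k_of_aa == k]]
    vals <- vals[!is.na(vals)]
    if (!length(vals)) return(NA_real_)
    mean(vals)
  }
  f2 <- class_mean(2); f3 <- class_mean(3)
  f4 <- class_mean(4); f6 <- class_mean(6)
  if (is.na(f3) && !is.na(f2) && !is.na(f4)) {
    # Wright's imputation for a genome/gene without usable Ile counts
    f3 <- 1 / ((1 / f2 + 1 / f4) / 2)
  }
  m <- table(factor(k_of_aa, levels = c(1, 2, 3, 4, 6)))
  terms <- c(`2` = f2, `3` = f3, `4` = f4, `6` = f6)
  present <- !is.na(terms) & terms > 0
  if (!any(present)) {
    warning("no degeneracy class with computable homozygosity; Nc undefined")
    return(NA_real_)
  }
  if (any(!present & m[c("2", "3", "4", "6")] > 0)) {
    warning("Nc computed with missing degeneracy class(es); value partial")
  }
  nc <- as.numeric(m["1"]) +
    sum(as.numeric(m[names(terms)[present]]) / terms[present])
  if (nc > length(code$codons)) {
    warning("Nc exceeds the number of sense codons (small-sample artifact)")
  }
  nc
}
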