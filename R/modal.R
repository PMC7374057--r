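#' Modal codon usage of a gene set
#'
#' Estimates the modal codon usage of a collection of genes: the usage of
#' the largest subset of genes that share a common codon-usage pattern,
#' rather than the pooled average (which a minority of atypical genes can
#' distort). The iterative scheme starts from the pooled usage, scores each
#' gene's consistency with the current candidate by a per-amino-acid
#' multinomial likelihood-ratio statistic G = 2 * sum n_c log(n_c / (N_aa
#' q_c)) with a chi-square p-value (df = sum over observed families of
#' (k - 1)), keeps the genes with p > `p_cutoff`, re-pools, and iterates to
#' a fixed point (identical accepted set on consecutive iterations).
#'
#' @param counts A `codon_counts` matrix with at least 2 genes.
#' @param p_cutoff Consistency p-value threshold in (0, 1); default 0.1.
#' @param max_iter Maximum number of re-pooling iterations.
#' @param code A [genetic_code()].
#'
#' @return Object of class `modal_usage`: list with `profile` (a
#'   [usage_profile()] of the accepted pool), `accepted_genes`,
#'   `iterations`, `converged`, and `p_values` (final per-gene p-values).
#'
#' @examples
#' set.seed(1)
#' seqs <- replicate(20, paste(sample(c("AAA", "AAG", "GAA"), 60, TRUE,
#'   prob = c(0.6, 0.2, 0.2)), collapse = ""))
#' names(seqs) <- paste0("g", 1:20)
#' m <- modal_usage(count_codons(seqs))
#' m$converged
#' @export
modal_usage <- function(counts, p_cutoff = 0.1, max_iter = 50L,
                        code = genetic_code()) {
  if (!is.matrix(counts) || nrow(counts) < 2) {
    stop("modal usage needs a count matrix with at least 2 genes")
  }
  if (p_cutoff <= 0 || p_cutoff >= 1) stop("p_cutoff must be in (0, 1)")
  counts <- counts[, code$codons, drop = FALSE]
  aa <- codon_aa(code, code$codons)
  fam_ind <- outer(aa, names(code$families), "==") * 1  # 61 x 20
  dimnames(fam_ind) <- list(code$codons, names(code$families))
  k <- code$degeneracy[aa]                               # per codon

  accepted <- rownames(counts)
  iter <- 0L
  converged <- FALSE
  pvals <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    pool <- colSums(counts[accepted, , drop = FALSE])
    q <- candidate_cuf(pool, aa)
    pvals <- gene_consistency_p(counts, q, aa, fam_ind, code)
    new_accept <- rownames(counts)[pvals > p_cutoff]
    if (!length(new_accept)) {
      stop("no gene consistent with the candidate modal usage; ",
           "consider a larger p_cutoff")
    }
    if (identical(sort(new_accept), sort(accepted))) {
      converged <- TRUE
      break
    }
    accepted <- new_accept
  }
  pool <- colSums(counts[accepted, , drop = FALSE])
  structure(
    list(profile = usage_profile(pool, code),
         accepted_genes = accepted,
         iterations = iter,
         converged = converged,
         p_values = pvals),
    class = "modal_usage"
  )
}

# candidate CUF with a 1e-6 floor (renormalized per family) so that genes
# using a codon the candidate pool lacks still get a finite statistic
candidate_cuf <- function(pool, aa) {
  q <- numeric(length(pool))
  names(q) <- names(pool)
  for (a in unique(aa)) {
    idx <- aa == a
    tot <- sum(pool[idx])
    if (tot > 0) {
      v <- pmax(pool[idx] / tot, 1e-6)
    } else {
      v <- rep(1, sum(idx))  # family unseen in pool: uniform candidate
    }
    q[idx] <- v / sum(v)
  }
  q
}

# vectorized per-gene likelihood-ratio consistency p-values; the G
# statistic carries the Williams small-sample correction per family
# (G / (1 + (k+1)/(6 n))), without which the chi-square approximation is
# anti-conservative for the rare amino acids of a ~300-codon gene
gene_consistency_p <- function(counts, q, aa, fam_ind, code) {
  n_gene <- nrow(counts)
  n_fam <- ncol(fam_ind)
  fam_tot <- counts %*% fam_ind                       # genes x 20
  expected <- (fam_tot %*% t(fam_ind)) *
    matrix(q, n_gene, ncol(counts), byrow = TRUE)
  term <- 2 * counts * log(counts / expected)
  term[counts == 0] <- 0
  k_fam <- code$degeneracy[colnames(fam_ind)]
  g_fam <- term %*% fam_ind                           # per-family G
  qw <- 1 + matrix(k_fam + 1, n_gene, n_fam, byrow = TRUE) /
    (6 * pmax(fam_tot, 1))
  degenerate <- matrix(k_fam, n_gene, n_fam, byrow = TRUE) > 1
  g <- rowSums((g_fam / qw) * (fam_tot > 0) * degenerate)
  # df: for each degenerate family observed in the gene, (family size - 1)
  df <- as.numeric((fam_tot > 0) %*% pmax(k_fam - 1, 0))
  p <- ifelse(df > 0, stats::pchisq(pmax(g, 0), df, lower.tail = FALSE), 1)
  names(p) <- rownames(counts)
  p
}

#' @export
print.modal_usage <- function(x, ...) {
  cat("Modal codon usage:", length(x$accepted_genes), "genes accepted in",
      x$iterations, "iteration(s)",
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(x$profile)
  invisible(x)
}

#' Artificial modal sequence
#'
#' Emits a deterministic coding sequence whose codon counts realize a given
#' usage profile as closely as integer rounding allows. Lengths default to
#' 10020 codons so that even codons of rare amino acids are represented
#' accurately; amino-acid counts and within-family codon counts are both
#' assigned by largest-remainder rounding, and codons are laid out grouped
#' by amino acid (alphabetical) with family codons in alphabetical order,
#' so the output is reproducible byte-for-byte.
#'
#' @param profile A `usage_profile` with defined CUF for every amino acid
#'   of positive frequency.
#' @param aa_freq Amino-acid frequencies to realize; defaults to the
#'   profile's own composition.
#' @param min_codons Minimum number of codons (default 10000; the default
#'   emitted length is 10020, the smallest convenient multiple above it).
#' @param code A [genetic_code()].
#' @return A single character string of `>= min_codons` codons.
#' @export
modal_sequence <- function(profile, aa_freq = profile$aa_freq,
                           min_codons = 10000L, code = genetic_code()) {
  len <- if (min_codons <= 10020L) 10020L else as.integer(min_codons)
  af <- aa_freq[aa_freq > 0]
  af <- af[order(names(af))]
  undef <- vapply(names(af), function(a) {
    any(is.na(profile$cuf[code$families[[a]]]))
  }, logical(1))
  if (any(undef)) {
    stop("amino acid(s) with positive frequency but undefined CUF: ",
         paste(names(af)[undef], collapse = ", "))
  }
  n_aa <- largest_remainder(af, len)
  parts <- character(0)
  for (a in names(af)) {
    fam <- code$families[[a]]   # alphabetical already
    n_cod <- largest_remainder(profile$cuf[fam], n_aa[[a]])
    parts <- c(parts, rep(fam, times = n_cod))
  }
  paste(parts, collapse = "")
}
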