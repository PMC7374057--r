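#' Codon-anticodon pairing table
#'
#' Enumerates, for every sense codon, the anticodons that can decode it and
#' the pairing class of the third-base interaction. Anticodons are written
#' 5'->3', so the first anticodon base (position 34) reads the codon's
#' third base. Watson-Crick classes (G34:C3, U34:A3, C34:G3) carry a fixed
#' penalty of 0; the remaining classes are the trainable wobble penalties:
#' `AU` (A34 reading U3, the Watson-Crick slot usually occupied by
#' inosine-modified A34), `GU` (G34:U3), `IC` (A34-as-inosine reading C3),
#' `IA` (A34-as-inosine reading A3) and `UG` (U34:G3). The nonstandard
#' U34:U3 interaction is deliberately not part of the table.
#'
#' @param code A [genetic_code()].
#' @return Data frame with columns `codon`, `anticodon`, `class` (one of
#'   WC, AU, GU, IC, IA, UG).
#' @export
pairing_table <- function(code = genetic_code()) {
  rules <- list(  # codon third base -> list of (anticodon 34 base, class)
    T = list(c("A", "AU"), c("G", "GU")),
    C = list(c("G", "WC"), c("A", "IC")),
    A = list(c("T", "WC"), c("A", "IA")),
    G = list(c("C", "WC"), c("T", "UG"))
  )
  out <- list()
  for (cod in code$codons) {
    third <- substr(cod, 3, 3)
    stem <- revcomp(substr(cod, 1, 2))  # anticodon positions 35-36
    for (rule in rules[[third]]) {
      out[[length(out) + 1L]] <- data.frame(
        codon = cod, anticodon = paste0(rule[1], stem), class = rule[2],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Wobble pairing penalties (Sij)
#'
#' Constructs the vector of pairing-efficiency penalties used by
#' [absolute_adaptiveness()]. Each penalty lies in [0, 1]; 0 means the
#' pairing is as efficient as Watson-Crick, 1 disables it. Defaults follow
#' the commonly used bacterial estimates of dos Reis-style analyses and
#' are meant to be replaced by organism-specific values from [train_sij()].
#'
#' @param AU,GU,IC,IA,UG Penalties for the five trainable pairing classes
#'   (see [pairing_table()]).
#' @return Named numeric vector of class `sij_weights`.
#' @export
sij_weights <- function(AU = 0, GU = 0.41, IC = 0.28, IA = 0.9999,
                        UG = 0.68) {
  s <- c(AU = AU, GU = GU, IC = IC, IA = IA, UG = UG)
  if (any(s < 0 | s > 1)) stop("Sij penalties must lie in [0, 1]")
  structure(s, class = "sij_weights")
}

#' Absolute and relative codon adaptiveness (Wi / wi)
#'
#' For each sense codon i, the absolute adaptiveness is
#' W_i = sum over allowed pairings j of (1 - s_class(i,j)) * tGCN_j, where
#' tGCN_j is the gene copy number of the tRNA with anticodon j; relative
#' adaptiveness w_i = W_i / max(W). Codons with W = 0 (not decodable by
#' the pool under the pairing table) receive the geometric mean of the
#' nonzero w values and are flagged.
#'
#' @param pool Named non-negative numeric vector of tRNA gene copy numbers
#'   keyed by anticodon (5'->3' triplets; U accepted), or a data frame with
#'   columns `anticodon` and `copy_number`.
#' @param s An [sij_weights()] vector.
#' @param code A [genetic_code()].
#' @return Data frame of class `adaptiveness` with columns `codon`, `W`,
#'   `w`, `substituted`.
#' @export
absolute_adaptiveness <- function(pool, s = sij_weights(),
                                  code = genetic_code()) {
  if (is.data.frame(pool)) {
    pool <- stats::setNames(pool$copy_number, pool$anticodon)
  }
  names(pool) <- normalize_dna(names(pool))
  if (!length(pool) || all(pool <= 0)) stop("empty tRNA pool")
  if (any(nchar(names(pool)) != 3) ||
      any(!grepl("^[ACGT]{3}$", names(pool)))) {
    stop("anticodons must be ACGU/T triplets")
  }
  pt <- pairing_table(code)
  eff <- ifelse(pt$class == "WC", 1, 1 - unclass(s)[pt$class])
  tgcn <- ifelse(pt$anticodon %in% names(pool), pool[pt$anticodon], 0)
  W <- tapply(eff * tgcn, factor(pt$codon, levels = code$codons), sum)
  W <- as.numeric(W)
  if (max(W) <= 0) stop("pool decodes nothing under the pairing table")
  w <- W / max(W)
  substituted <- w == 0
  if (any(substituted)) {
    w[substituted] <- exp(mean(log(w[!substituted])))
  }
  structure(
    data.frame(codon = code$codons, W = W, w = w, substituted = substituted,
               stringsAsFactors = FALSE),
    class = c("adaptiveness", "data.frame")
  )
}

# w vector (named by codon) out of an adaptiveness table
adapt_w <- function(adapt) {
  stats::setNames(adapt$w, adapt$codon)
}

#' Codon preference profile implied by an adaptiveness table
#'
#' Normalizes the relative adaptiveness w within each synonymous family,
#' giving the usage profile a genome perfectly adapted to the tRNA pool
#' would gravitate to. Together with [derive_trna_pool()] this closes the
#' loop between planted tRNA pools and planted codon preferences in
#' synthetic genomes.
#'
#' @param adapt An [absolute_adaptiveness()] table.
#' @param aa_freq Amino-acid composition for the resulting profile.
#' @param code A [genetic_code()].
#' @return A [usage_profile()].
#' @export
profile_from_adaptiveness <- function(adapt, aa_freq = default_aa_freq(),
                                      code = genetic_code()) {
  w <- adapt_w(adapt)[code$codons]
  aa <- codon_aa(code, code$codons)
  cuf <- numeric(0)
  for (fam in code$families) {
    cuf <- c(cuf, stats::setNames(w[fam] / sum(w[fam]), fam))
  }
  profile_from_cuf(cuf, aa_freq, code)
}

#' tRNA adaptation index of genes
#'
#' tAI of each gene: the geometric mean of the relative adaptiveness w over
#' the gene's codons with multiplicity, exp(sum n_c log w_c / sum n_c).
#'
#' @param counts Codon counts: a `codon_counts` matrix (one value per row)
#'   or a single named vector.
#' @param adapt An [absolute_adaptiveness()] table.
#' @param code A [genetic_code()].
#' @return Numeric vector of tAI values in (0, 1].
#' @export
gene_tai <- function(counts, adapt, code = genetic_code()) {
  w <- adapt_w(adapt)[code$codons]
  if (!is.matrix(counts)) {
    counts <- matrix(as_count_vector(counts, code), 1,
                     dimnames = list(NULL, code$codons))
  }
  counts <- counts[, code$codons, drop = FALSE]
  n <- rowSums(counts)
  if (any(n == 0)) stop("gene(s) with no sense codons")
  as.numeric(exp((counts %*% log(w)) / n))
}

#' Modal tRNA adaptation index (m-tAI)
#'
#' Scores a whole usage profile against an adaptiveness table: the weighted
#' geometric mean exp(sum q_c log w_c) with q_c = aa_freq(aa(c)) * cuf(c).
#' For a profile realized as a long modal sequence this equals the
#' sequence's [gene_tai()] up to rounding.
#'
#' @param profile A `usage_profile` with defined CUF for every amino acid
#'   of positive frequency.
#' @param adapt An [absolute_adaptiveness()] table.
#' @param code A [genetic_code()].
#' @return m-tAI in (0, 1].
#' @export
modal_tai <- function(profile, adapt, code = genetic_code()) {
  w <- adapt_w(adapt)[code$codons]
  aa <- codon_aa(code, code$codons)
  af <- profile$aa_freq[aa]
  q <- as.numeric(af) * profile$cuf
  bad <- af > 0 & is.na(profile$cuf)
  if (any(bad)) {
    stop("undefined CUF for amino acid(s) with positive frequency: ",
         paste(unique(aa[bad]), collapse = ", "))
  }
  q[is.na(q)] <- 0
  exp(sum(q * log(w)) / sum(q))
}

#' Directional codon bias score (DCBS)
#'
#' Per-gene deviation of codon frequencies from the product of the gene's
#' positional nucleotide frequencies: with f(xyz) the codon frequency and
#' f1, f2, f3 the nucleotide frequencies at the three codon positions
#' (computed over the gene's sense codons), each codon scores
#' d = max(f/(f1 f2 f3), (f1 f2 f3)/f) and DCBS is the mean of d over the
#' gene's codons with multiplicity. DCBS >= 1, with 1 meaning codon usage
#' fully explained by nucleotide composition.
#'
#' @param counts Codon counts: matrix (one value per row) or named vector.
#' @param code A [genetic_code()].
#' @return Numeric vector of DCBS values (>= 1).
#' @export
gene_dcbs <- function(counts, code = genetic_code()) {
  if (!is.matrix(counts)) {
    counts <- matrix(as_count_vector(counts, code), 1,
                     dimnames = list(NULL, code$codons))
  }
  counts <- counts[, code$codons, drop = FALSE]
  b1 <- substr(code$codons, 1, 1)
  b2 <- substr(code$codons, 2, 2)
  b3 <- substr(code$codons, 3, 3)
  bases <- c("A", "C", "G", "T")
  ind1 <- outer(b1, bases, "==") * 1
  ind2 <- outer(b2, bases, "==") * 1
  ind3 <- outer(b3, bases, "==") * 1
  n <- rowSums(counts)
  if (any(n == 0)) stop("gene(s) with no sense codons")
  f <- counts / n
  f1 <- (counts %*% ind1) / n
  f2 <- (counts %*% ind2) / n
  f3 <- (counts %*% ind3) / n
  colnames(f1) <- colnames(f2) <- colnames(f3) <- bases
  expv <- f1[, b1, drop = FALSE] * f2[, b2, drop = FALSE] *
    f3[, b3, drop = FALSE]
  ratio <- f / expv
  d <- pmax(ratio, 1 / ratio)
  d[counts == 0] <- 0           # only observed codons contribute
  as.numeric(rowSums(counts * d) / n)
}

#' Train wobble pairing penalties (Sij)
#'
#' Fits the five trainable pairing penalties of [sij_weights()] to a
#' genome by maximizing the Spearman rank correlation between the per-gene
#' DCBS (a tRNA-free measure of directional codon bias) and the per-gene
#' tAI computed under the candidate penalties, using Nelder-Mead from
#' multiple random starts drawn uniformly in [0,1]^5. Out-of-box proposals
#' are clipped to [0, 1] during evaluation. The best restart is returned.
#'
#' @param counts `codon_counts` matrix of the genome's genes.
#' @param pool tRNA pool (see [absolute_adaptiveness()]).
#' @param restarts Number of random starts (default 20).
#' @param seed Integer seed controlling the random starts; the caller's
#'   RNG state is left untouched.
#' @param max_iter Maximum Nelder-Mead iterations per start.
#' @param code A [genetic_code()].
#' @return Object of class `sij_fit`: list with `s` (an [sij_weights()]),
#'   `rho` (achieved Spearman correlation), `restarts`, `seed`,
#'   `start_objectives` and `convergence` codes.
#' @export
train_sij <- function(counts, pool, restarts = 20L, seed = 1L,
                      max_iter = 500L, code = genetic_code()) {
  if (!is.matrix(counts) || nrow(counts) < 2) {
    stop("need a count matrix with at least 2 genes")
  }
  if (nrow(counts) < 50) {
    warning("fewer than 50 genes; Sij training may be unstable")
  }
  dcbs <- gene_dcbs(counts, code)
  if (stats::sd(dcbs) == 0) stop("zero variance in DCBS across genes")
  pt <- pairing_table(code)
  w_classes <- c("AU", "GU", "IC", "IA", "UG")
  if (is.data.frame(pool)) {
    pool <- stats::setNames(pool$copy_number, pool$anticodon)
  }
  names(pool) <- normalize_dna(names(pool))
  tgcn <- ifelse(pt$anticodon %in% names(pool), pool[pt$anticodon], 0)
  cod_f <- factor(pt$codon, levels = code$codons)
  n <- rowSums(counts[, code$codons, drop = FALSE])
  cmat <- counts[, code$codons, drop = FALSE]

  objective <- function(par) {
    par <- pmin(pmax(par, 0), 1)
    s_full <- c(WC = 0, stats::setNames(par, w_classes))
    W <- as.numeric(tapply((1 - s_full[pt$class]) * tgcn, cod_f, sum))
    if (max(W) <= 0) return(-1)
    w <- W / max(W)
    if (any(w == 0)) w[w == 0] <- exp(mean(log(w[w > 0])))
    tai <- as.numeric(exp((cmat %*% log(w)) / n))
    if (stats::sd(tai) == 0) return(-1)
    stats::cor(dcbs, tai, method = "spearman")
  }

  runs <- with_seed(seed, {
    lapply(seq_len(restarts), function(i) {
      start <- stats::runif(length(w_classes))
      fit <- stats::optim(start, objective, method = "Nelder-Mead",
                          control = list(fnscale = -1, maxit = max_iter,
                                         reltol = 1e-6))
      list(start = start, start_obj = objective(start), par = fit$par,
           value = fit$value, convergence = fit$convergence)
    })
  })
  values <- vapply(runs, `[[`, numeric(1), "value")
  best <- runs[[which.max(values)]]
  par <- pmin(pmax(best$par, 0), 1)
  structure(
    list(s = sij_weights(AU = par[1], GU = par[2], IC = par[3],
                         IA = par[4], UG = par[5]),
         rho = best$value,
         restarts = restarts,
         seed = seed,
         start_objectives = vapply(runs, `[[`, numeric(1), "start_obj"),
         convergence = vapply(runs, `[[`, integer(1), "convergence")),
    class = "sij_fit"
  )
}

#' @export
print.sij_fit <- function(x, ...) {
  cat("Trained Sij wobble penalties (", x$restarts, " restarts, seed ",
      x$seed, ")\n", sep = "")
  print(round(unclass(x$s), 4))
  cat("  Spearman rho(DCBS, tAI) =", format(round(x$rho, 4)), "\n")
  invisible(x)
}
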