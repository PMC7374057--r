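# shared fixtures and small independent oracles for the suite

CODE <- genetic_code()
AA_OF <- CODE$codon_to_aa[CODE$codons]

# overall codon-frequency distribution of a profile (sums to 1); the scale
# on which profile L1 distances are quoted
q_dist <- function(profile) {
  q <- profile$aa_freq[AA_OF] * profile$cuf
  q[is.na(q)] <- 0
  as.numeric(q)
}

l1_profiles <- function(p1, p2) sum(abs(q_dist(p1) - q_dist(p2)))

# random in-frame stop-free CDS of n codons
random_cds <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(CODE$codons, n, replace = TRUE), collapse = "")
}

# adaptiveness table with prescribed w values (for tAI arithmetic tests)
make_adapt <- function(w) {
  stopifnot(!is.null(names(w)))
  full <- setNames(rep(1, length(CODE$codons)), CODE$codons)
  full[names(w)] <- w
  structure(data.frame(codon = CODE$codons, W = full, w = full,
                       substituted = FALSE, stringsAsFactors = FALSE),
            class = c("adaptiveness", "data.frame"))
}

revcomp_oracle <- function(x) {
  vapply(strsplit(chartr("ACGT", "TGCA", x), ""),
         function(ch) paste(rev(ch), collapse = ""), "")
}

# brute-force per-position codon scan, independent of count_codons
oracle_sense_codon_count <- function(seq) {
  seq <- toupper(seq)
  n <- 0L
  for (i in seq(1, nchar(seq) - 2, by = 3)) {
    cod <- substr(seq, i, i + 2)
    if (!grepl("^[ACGT]{3}$", cod)) next
    if (CODE$codon_to_aa[cod] == "*") next
    n <- n + 1L
  }
  n
}

# independent CA oracle: eigen-decomposition of t(S) %*% S
oracle_ca <- function(mat) {
  n <- sum(mat)
  p <- mat / n
  r <- rowSums(p)
  cc <- colSums(p)
  s <- diag(1 / sqrt(r)) %*% (p - outer(r, cc)) %*% diag(1 / sqrt(cc))
  ev <- eigen(t(s) %*% s, symmetric = TRUE)
  keep <- ev$values > max(ev$values) * 1e-12
  v <- ev$vectors[, keep, drop = FALSE]
  d <- sqrt(ev$values[keep])
  # row principal coordinates via the transition formula
  f <- diag(1 / r) %*% (p - outer(r, cc)) %*% diag(1 / sqrt(cc)) %*% v
  list(row_coords = f, inertia = ev$values[keep], sv = d,
       col_standard = diag(1 / sqrt(cc)) %*% v)
}

# align columns of two coordinate matrices up to per-dimension sign
match_signs <- function(a, b) {
  for (k in seq_len(ncol(a))) {
    if (sum(abs(a[, k] - b[, k])) > sum(abs(a[, k] + b[, k]))) {
      b[, k] <- -b[, k]
    }
  }
  b
}
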