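#' Reference amino-acid composition
#'
#' A realistic average bacterial proteome composition used as the default
#' by the synthetic-genome generator and the modal-sequence emitter.
#'
#' @return Named numeric vector over the 20 amino acids, summing to 1.
#' @export
default_aa_freq <- function() {
  c(A = 0.095, C = 0.012, D = 0.054, E = 0.058, F = 0.039, G = 0.074,
    H = 0.022, I = 0.060, K = 0.044, L = 0.105, M = 0.028, N = 0.040,
    P = 0.043, Q = 0.044, R = 0.055, S = 0.058, T = 0.054, V = 0.073,
    W = 0.014, Y = 0.028)
}

# profile with the same third-base weights in every family
third_base_profile <- function(weights, aa_freq, code) {
  cuf <- numeric(0)
  for (fam in code$families) {
    w <- weights[substr(fam, 3, 3)]
    cuf <- c(cuf, stats::setNames(w / sum(w), fam))
  }
  profile_from_cuf(cuf, aa_freq, code)
}

#' Mutational codon-preference profile
#'
#' Emulates usage driven purely by an AT-leaning mutational bias: every
#' synonymous family weights its codons by third base with A > U > G > C.
#' This is the profile the least-selected genes (singletons) gravitate to
#' in the synthetic genomes.
#'
#' @param aa_freq Amino-acid composition (default [default_aa_freq()]).
#' @param code A [genetic_code()].
#' @return A [usage_profile()].
#' @export
mutational_profile <- function(aa_freq = default_aa_freq(),
                               code = genetic_code()) {
  third_base_profile(c(A = 0.35, T = 0.30, G = 0.20, C = 0.15),
                     aa_freq, code)
}

#' Unbiased codon-preference profile
#'
#' Uniform usage within every synonymous family; the natural "no
#' directional bias" end point for mixtures used in adaptation-training
#' experiments (per-gene DCBS is close to 1 for genes drawn from it).
#'
#' @param aa_freq Amino-acid composition (default [default_aa_freq()]).
#' @param code A [genetic_code()].
#' @return A [usage_profile()].
#' @export
uniform_profile <- function(aa_freq = default_aa_freq(),
                            code = genetic_code()) {
  third_base_profile(c(A = 1, C = 1, G = 1, T = 1), aa_freq, code)
}

#' Selected (tRNA-adapted) codon-preference profile
#'
#' The profile towards which selection pulls the synthetic genes: C-ending
#' codons dominate the pyrimidine-ending 2-fold families and 3-fold Ile
#' (the C bias), U-ending codons dominate the 4-fold boxes (the U bias),
#' and the purine-ending 2-fold families prefer G. A matching tRNA pool
#' can be derived with [derive_trna_pool()].
#'
#' @param aa_freq Amino-acid composition (default [default_aa_freq()]).
#' @param code A [genetic_code()].
#' @return A [usage_profile()].
#' @export
selected_profile <- function(aa_freq = default_aa_freq(),
                             code = genetic_code()) {
  four_w <- c(T = 0.45, C = 0.30, G = 0.15, A = 0.10)
  cuf <- numeric(0)
  for (a in names(code$families)) {
    fam <- code$families[[a]]
    k <- length(fam)
    third <- substr(fam, 3, 3)
    if (k == 1) {
      v <- stats::setNames(1, fam)
    } else if (k == 2 && all(third %in% c("T", "C"))) {
      v <- stats::setNames(ifelse(third == "C", 0.75, 0.25), fam)
    } else if (k == 2) {                      # purine-ending: K, E, Q
      v <- stats::setNames(ifelse(third == "G", 0.70, 0.30), fam)
    } else if (k == 3) {                      # Ile
      v <- stats::setNames(c(0.10, 0.55, 0.35)[match(third, c("A", "C", "T"))],
                           fam)
    } else if (k == 4) {
      v <- stats::setNames(four_w[third], fam)
    } else {                                  # 6-fold: L, S, R
      prefix <- substr(fam, 1, 2)
      box4 <- names(which(table(prefix) == 4))
      v <- stats::setNames(numeric(k), fam)
      in4 <- prefix == box4
      v[in4] <- 0.8 * four_w[third[in4]] / sum(four_w)
      two <- fam[!in4]
      t3 <- substr(two, 3, 3)
      if (all(t3 %in% c("T", "C"))) {         # Ser AGT/AGC
        v[two] <- ifelse(t3 == "C", 0.12, 0.08)
      } else {                                # Leu UUR / Arg AGR
        v[two] <- ifelse(t3 == "G", 0.15, 0.05)
      }
    }
    cuf <- c(cuf, v / sum(v))
  }
  profile_from_cuf(cuf, aa_freq, code)
}

#' Shift four-fold boxes towards U-ending codons
#'
#' Moves `shift` units of within-family CUF mass onto the U-ending codon
#' of every four-codon box that encodes a single amino acid (the 4-fold
#' families and the 4-fold boxes of Leu, Ser, Arg), taking the mass from
#' the G-ending codon first and the C-ending codon for any remainder.
#' Used to give the PHE set of a synthetic genome the extra U bias that
#' distinguishes it from the most ancestral core in biphasic (group B)
#' genomes.
#'
#' @param profile A [usage_profile()].
#' @param shift CUF mass to move (capped at the available G+C mass).
#' @param code A [genetic_code()].
#' @return The shifted `usage_profile`.
#' @export
apply_u_shift <- function(profile, shift, code = genetic_code()) {
  cuf <- profile$cuf
  for (a in names(code$families)) {
    fam <- code$families[[a]]
    prefix <- substr(fam, 1, 2)
    for (box in names(which(table(prefix) == 4))) {
      g_cod <- fam[prefix == box & substr(fam, 3, 3) == "G"]
      c_cod <- fam[prefix == box & substr(fam, 3, 3) == "C"]
      t_cod <- fam[prefix == box & substr(fam, 3, 3) == "T"]
      if (anyNA(cuf[c(g_cod, c_cod, t_cod)])) next
      mv_g <- min(shift, cuf[g_cod])
      mv_c <- min(shift - mv_g, cuf[c_cod])
      cuf[g_cod] <- cuf[g_cod] - mv_g
      cuf[c_cod] <- cuf[c_cod] - mv_c
      cuf[t_cod] <- cuf[t_cod] + mv_g + mv_c
    }
  }
  profile_from_cuf(cuf[!is.na(cuf)], profile$aa_freq, code)
}

#' Synthetic genome configuration
#'
#' Assembles the configuration consumed by [generate_genome()]: the gene
#' sets with their sizes and selection intensities (`mix` = weight of the
#' selected profile in the per-family CUF mixture), the two codon
#' preference profiles, gene-length distribution and abundance model.
#'
#' @param sets Data frame with columns `set`, `size`, `mix` (mix in
#'   [0, 1], monotone from singletons to PHE when emulating the
#'   ancestry-graded pattern).
#' @param mut_profile,sel_profile The mixture end points.
#' @param aa_freq Amino-acid composition of the genes.
#' @param len_meanlog,len_sdlog,min_len Log-normal codon-length
#'   distribution (median 300 codons by default) and lower bound.
#' @param phe_u_shift Extra U-bias (see [apply_u_shift()]) applied to sets
#'   named `"PHE"`; 0 disables.
#' @param abund_base,abund_slope,abund_sd Log10-abundance model:
#'   base + slope * mix + Normal(0, sd).
#' @param seed Mandatory integer seed.
#' @return List of class `genome_sim_config`.
#' @export
genome_sim_config <- function(sets,
                              mut_profile = mutational_profile(),
                              sel_profile = selected_profile(),
                              aa_freq = default_aa_freq(),
                              len_meanlog = log(300), len_sdlog = 0.25,
                              min_len = 50L, phe_u_shift = 0,
                              abund_base = 1, abund_slope = 3,
                              abund_sd = 0.3, seed = 1L) {
  stopifnot(is.data.frame(sets),
            all(c("set", "size", "mix") %in% names(sets)),
            all(sets$mix >= 0 & sets$mix <= 1), all(sets$size >= 1))
  structure(
    list(sets = sets, mut_profile = mut_profile, sel_profile = sel_profile,
         aa_freq = aa_freq, len_meanlog = len_meanlog,
         len_sdlog = len_sdlog, min_len = as.integer(min_len),
         phe_u_shift = phe_u_shift, abund_base = abund_base,
         abund_slope = abund_slope, abund_sd = abund_sd,
         seed = as.integer(seed)),
    class = "genome_sim_config"
  )
}

#' Preset: ancestry-graded biphasic (group B style) genome
#'
#' Singletons, core sets C1..Cn of increasing ancestry and a PHE set, with
#' selection intensity rising monotonically along that order and the PHE
#' set carrying an extra U bias in the four-fold boxes, reproducing the
#' biphasic GC3 pattern (GC3 peaks at the most ancestral core, then drops
#' toward PHE).
#'
#' @param seed Integer seed.
#' @param n_core Number of core sets (default 4).
#' @param set_size Genes per set (default 150).
#' @return A [genome_sim_config()].
#' @export
group_b_config <- function(seed = 1L, n_core = 4L, set_size = 150L) {
  mixes <- seq(0.25, 0.85, length.out = n_core)
  sets <- data.frame(
    set = c("singletons", paste0("C", seq_len(n_core)), "PHE"),
    size = set_size,
    mix = c(0.05, mixes, 1),
    stringsAsFactors = FALSE)
  genome_sim_config(sets, phe_u_shift = 0.18, seed = seed)
}

#' Generate a synthetic genome
#'
#' Draws every gene's amino-acid sequence from the configured composition
#' and its codons, per amino acid, from the set-specific CUF mixture
#' (1 - mix) * mutational + mix * selected; emits protein abundances
#' correlated with the selection intensity so that PHE-like genes are
#' abundant. Fully reproducible from the config seed.
#'
#' @param cfg A [genome_sim_config()].
#' @param code A [genetic_code()].
#' @return List with `sequences` (named character vector of CDS, no stop
#'   codons), `partition` (data frame gene/set), `abundance` (named
#'   vector), and `set_mix`.
#' @export
generate_genome <- function(cfg, code = genetic_code()) {
  stopifnot(inherits(cfg, "genome_sim_config"))
  aa_names <- names(cfg$aa_freq[cfg$aa_freq > 0])
  with_seed(cfg$seed, {
    seqs <- character(0)
    genes <- character(0)
    set_of <- character(0)
    abund <- numeric(0)
    for (r in seq_len(nrow(cfg$sets))) {
      set <- cfg$sets$set[r]
      m <- cfg$sets$mix[r]
      sel <- cfg$sel_profile
      if (cfg$phe_u_shift > 0 && set == "PHE") {
        sel <- apply_u_shift(sel, cfg$phe_u_shift, code)
      }
      cuf_mix <- (1 - m) * cfg$mut_profile$cuf + m * sel$cuf
      for (g in seq_len(cfg$sets$size[r])) {
        len <- max(cfg$min_len,
                   round(stats::rlnorm(1, cfg$len_meanlog, cfg$len_sdlog)))
        aa_seq <- sample(aa_names, len, replace = TRUE,
                         prob = cfg$aa_freq[aa_names])
        cods <- character(len)
        for (a in unique(aa_seq)) {
          idx <- aa_seq == a
          fam <- code$families[[a]]
          cods[idx] <- sample(fam, sum(idx), replace = TRUE,
                              prob = cuf_mix[fam])
        }
        id <- sprintf("%s_g%04d", set, g)
        genes <- c(genes, id)
        set_of <- c(set_of, set)
        seqs <- c(seqs, stats::setNames(paste(cods, collapse = ""), id))
        abund <- c(abund, stats::setNames(
          10^(cfg$abund_base + cfg$abund_slope * m +
                stats::rnorm(1, 0, cfg$abund_sd)), id))
      }
    }
    list(sequences = seqs,
         partition = data.frame(gene = genes, set = set_of,
                                stringsAsFactors = FALSE),
         abundance = abund,
         set_mix = stats::setNames(cfg$sets$mix, cfg$sets$set))
  })
}

#' Derive a tRNA pool consistent with a selected profile
#'
#' Inverts the adaptiveness-to-preference relation so that planted codon
#' preferences are tRNA-consistent, mimicking the sparse anticodon
#' repertoires of real genomes. Within every codon box (codons sharing
#' their first two bases and amino acid), usage weight is routed to a
#' decoder anticodon: C-, A- and G-ending codons feed their Watson-Crick
#' anticodons (G34, U34, C34); a U-ending codon feeds an inosine-style A34
#' anticodon when it is the most used codon of its box, and otherwise the
#' box's G34 wobble reader. Copy numbers are assigned by
#' largest-remainder rounding of these weights to `total_genes`, and any
#' codon left without a usable decoder gets its Watson-Crick anticodon
#' bumped to one copy (full-decoding guarantee).
#'
#' @param sel_profile The planted selected [usage_profile()].
#' @param total_genes Approximate total tRNA gene count to distribute
#'   (default 120, a typical bacterial magnitude).
#' @param code A [genetic_code()].
#' @return Named integer vector: anticodon -> gene copy number.
#' @export
derive_trna_pool <- function(sel_profile, total_genes = 120L,
                             code = genetic_code()) {
  cuf <- sel_profile$cuf
  cuf[is.na(cuf)] <- 0
  names(cuf) <- code$codons
  weight <- stats::setNames(numeric(length(code$codons)),
                            revcomp(code$codons))
  for (fam in code$families) {
    boxes <- split(fam, substr(fam, 1, 2))
    for (box in boxes) {
      third <- substr(box, 3, 3)
      for (i in seq_along(box)) {
        cod <- box[i]
        wc <- revcomp(cod)
        if (third[i] != "T") {
          weight[wc] <- weight[wc] + cuf[cod]
        } else if (cuf[cod] == max(cuf[box])) {
          weight[wc] <- weight[wc] + cuf[cod]        # inosine-style A34
        } else {
          g34 <- revcomp(sub("T$", "C", cod))        # box G34 wobble reader
          weight[g34] <- weight[g34] + cuf[cod]
        }
      }
    }
  }
  tgcn <- largest_remainder(weight, total_genes)
  # full-decoding guarantee: every codon needs some usable decoder
  pt <- pairing_table(code)
  usable <- pt$class != "IA"   # the near-disabled inosine:A pairing
  anticodons <- revcomp(code$codons)
  for (i in seq_along(code$codons)) {
    acs <- intersect(pt$anticodon[usable & pt$codon == code$codons[i]],
                     names(tgcn))
    if (!length(acs) || all(tgcn[acs] == 0)) {
      tgcn[anticodons[i]] <- max(tgcn[anticodons[i]], 1L)
    }
  }
  tgcn[tgcn > 0]
}

#' F3x4 equilibrium codon frequencies
#'
#' Codon frequencies as the product of the three positional nucleotide
#' frequencies, with stop-codon mass removed and the remainder
#' renormalized over the 61 sense codons (the standard F3x4 convention).
#'
#' @param x Either an in-frame nucleotide sequence (positional frequencies
#'   are estimated from it) or a 3 x 4 matrix of positional frequencies
#'   with columns named A, C, G, T.
#' @param code A [genetic_code()].
#' @return Named numeric vector over the 61 sense codons, summing to 1.
#' @export
f3x4_frequencies <- function(x, code = genetic_code()) {
  bases <- c("A", "C", "G", "T")
  if (is.character(x)) {
    s <- normalize_dna(x)
    if (nchar(s) %% 3L != 0L) stop("sequence not in frame")
    cods <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
    posf <- t(vapply(1:3, function(p) {
      tab <- table(factor(substr(cods, p, p), levels = bases))
      as.numeric(tab) / length(cods)
    }, numeric(4)))
    colnames(posf) <- bases
  } else {
    posf <- x[, bases, drop = FALSE]
    posf <- posf / rowSums(posf)
  }
  pi <- vapply(code$codons, function(cod) {
    posf[1, substr(cod, 1, 1)] * posf[2, substr(cod, 2, 2)] *
      posf[3, substr(cod, 3, 3)]
  }, numeric(1))
  pi / sum(pi)
}

# M0 (one-ratio) codon rate matrix, scaled to one expected substitution
# per codon per unit branch length at the equilibrium pi
m0_rate_matrix <- function(kappa, omega, pi, code = genetic_code()) {
  cods <- code$codons
  n <- length(cods)
  aa <- codon_aa(code, cods)
  b <- do.call(rbind, strsplit(cods, ""))
  Q <- matrix(0, n, n, dimnames = list(cods, cods))
  is_transition <- function(x, y) {
    (x == "A" & y == "G") | (x == "G" & y == "A") |
      (x == "C" & y == "T") | (x == "T" & y == "C")
  }
  for (i in seq_len(n)) {
    diffs <- sweep(b, 2, b[i, ], "!=")
    ndiff <- rowSums(diffs)
    js <- base::which(ndiff == 1)
    for (j in js) {
      pos <- base::which(diffs[j, ])
      rate <- pi[j]
      if (is_transition(b[i, pos], b[j, pos])) rate <- rate * kappa
      if (aa[i] != aa[j]) rate <- rate * omega
      Q[i, j] <- rate
    }
  }
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  if (scale <= 0) stop("degenerate rate matrix (omega = 0 and no synonymous moves?)")
  Q / scale
}

#' Evolve an ortholog family under the M0 codon model
#'
#' Simulates neutral-with-respect-to-codon-usage evolution of a root
#' coding sequence along a tree: a continuous-time codon substitution
#' process with a single transition/transversion ratio kappa, a single
#' nonsynonymous/synonymous rate ratio omega (the KA/KS of the model), and
#' F3x4 equilibrium frequencies, simulated site by site with exact
#' (Gillespie) event sampling. No indels are introduced, so the leaf
#' sequences are codon-aligned by construction.
#'
#' @param root In-frame, stop-free nucleotide sequence.
#' @param tree An [ape::phylo] tree or a Newick string; branch lengths in
#'   expected substitutions per codon.
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Nonsynonymous/synonymous rate ratio (>= 0).
#' @param pi Equilibrium codon frequencies; defaults to
#'   [f3x4_frequencies()] of the root.
#' @param seed Integer seed (local RNG stream).
#' @param code A [genetic_code()].
#' @return List with `leaf_seqs` (named character vector, one aligned CDS
#'   per tip), `root`, `tree`, and the model parameters.
#' @export
evolve_m0 <- function(root, tree, kappa = 2, omega = 0.2, pi = NULL,
                      seed = 1L, code = genetic_code()) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  s <- normalize_dna(root)
  if (nchar(s) %% 3L != 0L) stop("root not in frame")
  cods <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
  if (any(cods %in% code$stops)) stop("root contains stop codon(s)")
  if (is.null(pi)) pi <- f3x4_frequencies(s, code)
  pi <- pi[code$codons]
  Q <- m0_rate_matrix(kappa, omega, pi, code)
  lam <- -diag(Q)
  jump <- Q
  diag(jump) <- 0
  jump <- jump / ifelse(lam > 0, lam, 1)
  idx0 <- match(cods, code$codons)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode

  with_seed(seed, {
    seqs <- vector("list", nnode)
    root_node <- ntip + 1L
    seqs[[root_node]] <- idx0
    edges <- stats::reorder(tree, "cladewise")$edge
    lens <- stats::reorder(tree, "cladewise")$edge.length
    for (e in seq_len(nrow(edges))) {
      parent <- edges[e, 1]; child <- edges[e, 2]
      len <- lens[e]
      x <- seqs[[parent]]
      for (site in seq_along(x)) {
        t <- 0
        cur <- x[site]
        repeat {
          if (lam[cur] <= 0) break
          t <- t + stats::rexp(1, lam[cur])
          if (t >= len) break
          cur <- sample.int(length(lam), 1, prob = jump[cur, ])
        }
        x[site] <- cur
      }
      seqs[[child]] <- x
    }
    leaf_seqs <- vapply(seq_len(ntip), function(i) {
      paste(code$codons[seqs[[i]]], collapse = "")
    }, character(1))
    names(leaf_seqs) <- tree$tip.label
    list(leaf_seqs = leaf_seqs, root = s, tree = tree,
         kappa = kappa, omega = omega, pi = pi)
  })
}

#' Nei-Gojobori (1986) KA and KS
#'
#' Pathway-counting estimate of the nonsynonymous and synonymous
#' substitution rates between two aligned in-frame sequences: average
#' synonymous/nonsynonymous site counts over the two sequences (changes
#' creating stop codons excluded), pathway-averaged difference counts
#' (pathways through stop codons excluded), and the Jukes-Cantor multiple-
#' hit correction. Serves as the independent check that [evolve_m0()]
#' preserves the requested KA/KS.
#'
#' @param seq1,seq2 Aligned, equal-length, in-frame, stop-free sequences.
#' @param code A [genetic_code()].
#' @return List with `ka`, `ks`, `ratio`, raw counts (`S`, `N`, `Sd`,
#'   `Nd`), and a `saturated` flag (TRUE when a Jukes-Cantor argument is
#'   non-positive, leaving the estimate undefined).
#' @export
ng86_kaks <- function(seq1, seq2, code = genetic_code()) {
  s1 <- normalize_dna(seq1); s2 <- normalize_dna(seq2)
  if (nchar(s1) != nchar(s2)) stop("sequences differ in length")
  if (nchar(s1) %% 3L != 0L) stop("sequences not in frame")
  c1 <- substring(s1, seq(1L, nchar(s1), 3L), seq(3L, nchar(s1), 3L))
  c2 <- substring(s2, seq(1L, nchar(s2), 3L), seq(3L, nchar(s2), 3L))
  if (any(c(c1, c2) %in% code$stops)) stop("stop codon in input")

  site_counts <- function(cod) {
    aa0 <- code$codon_to_aa[cod]
    syn <- 0; nonsyn <- 0
    for (p in 1:3) {
      for (bchr in setdiff(c("A", "C", "G", "T"), substr(cod, p, p))) {
        alt <- cod
        substr(alt, p, p) <- bchr
        if (code$codon_to_aa[alt] == "*") next
        if (code$codon_to_aa[alt] == aa0) syn <- syn + 1 / 3
        else nonsyn <- nonsyn + 1 / 3
      }
    }
    c(syn, nonsyn)
  }
  sc1 <- vapply(c1, site_counts, numeric(2))
  sc2 <- vapply(c2, site_counts, numeric(2))
  S <- (sum(sc1[1, ]) + sum(sc2[1, ])) / 2
  N <- (sum(sc1[2, ]) + sum(sc2[2, ])) / 2

  path_diffs <- function(a, b) {
    pos <- base::which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    if (!length(pos)) return(c(0, 0))
    perms <- if (length(pos) == 1) list(pos) else {
      if (length(pos) == 2) list(pos, rev(pos)) else {
        idx <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                    c(3, 1, 2), c(3, 2, 1))
        lapply(idx, function(o) pos[o])
      }
    }
    tally <- function(order, allow_stop) {
      cur <- a; syn <- 0; nonsyn <- 0
      for (p in order) {
        nxt <- cur
        substr(nxt, p, p) <- substr(b, p, p)
        if (!allow_stop && code$codon_to_aa[nxt] == "*") return(NULL)
        if (code$codon_to_aa[nxt] == code$codon_to_aa[cur]) syn <- syn + 1
        else nonsyn <- nonsyn + 1
        cur <- nxt
      }
      c(syn, nonsyn)
    }
    res <- Filter(Negate(is.null), lapply(perms, tally, allow_stop = FALSE))
    if (!length(res)) res <- lapply(perms, tally, allow_stop = TRUE)
    Reduce(`+`, res) / length(res)
  }
  dd <- mapply(function(a, b) path_diffs(a, b), c1, c2)
  Sd <- sum(dd[1, ]); Nd <- sum(dd[2, ])

  jc <- function(p) {
    arg <- 1 - 4 * p / 3
    if (arg <= 0) return(NA_real_)
    -3 / 4 * log(arg)
  }
  ks <- jc(Sd / S)
  ka <- jc(Nd / N)
  saturated <- is.na(ks) || is.na(ka)
  ratio <- if (!saturated && ks > 0) ka / ks else NA_real_
  list(ka = ka, ks = ks, ratio = ratio, S = S, N = N, Sd = Sd, Nd = Nd,
       saturated = saturated)
}
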