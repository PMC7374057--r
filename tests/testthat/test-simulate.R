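test_that("genome generation is seed-reproducible and hits its mixture ends", {
  cfg <- genome_sim_config(
    data.frame(set = c("lo", "hi"), size = c(150, 150), mix = c(0, 1)),
    seed = 91)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1$sequences, g2$sequences)
  expect_identical(g1$abundance, g2$abundance)

  cnt <- count_codons(g1$sequences)
  bys <- split(g1$partition$gene, g1$partition$set)
  lo <- usage_profile(pool_counts(cnt, bys[["lo"]]))
  hi <- usage_profile(pool_counts(cnt, bys[["hi"]]))
  expect_lte(l1_profiles(lo, mutational_profile()), 0.03)
  expect_lte(l1_profiles(hi, selected_profile()), 0.03)

  # abundances correlate with the selection intensity
  expect_gt(median(g1$abundance[bys[["hi"]]]),
            10 * median(g1$abundance[bys[["lo"]]]))
})

test_that("F3x4 frequencies are stop-free products of positional frequencies", {
  set.seed(92)
  s <- random_cds(1500)
  pi <- f3x4_frequencies(s)
  expect_equal(sum(pi), 1)
  expect_setequal(names(pi), CODE$codons)
  expect_true(all(pi > 0))

  # direct product check for one codon
  cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  f1 <- mean(substr(cods, 1, 1) == "A")
  f2 <- mean(substr(cods, 2, 2) == "A")
  f3 <- mean(substr(cods, 3, 3) == "A")
  raw <- f1 * f2 * f3
  # normalization constant: total product mass on the 61 sense codons
  posf <- vapply(1:3, function(p) {
    vapply(c("A", "C", "G", "T"), function(b) mean(substr(cods, p, p) == b),
           numeric(1))
  }, numeric(4))
  z <- sum(apply(do.call(rbind, strsplit(CODE$codons, "")), 1, function(b) {
    posf[match(b[1], c("A", "C", "G", "T")), 1] *
      posf[match(b[2], c("A", "C", "G", "T")), 2] *
      posf[match(b[3], c("A", "C", "G", "T")), 3]
  }))
  expect_equal(unname(pi[["AAA"]]), raw / z)
})

test_that("the M0 generator matrix is a proper scaled rate matrix", {
  set.seed(93)
  pi <- f3x4_frequencies(random_cds(2000))
  Q <- codonsel:::m0_rate_matrix(2, 0.5, pi)
  expect_lt(max(abs(rowSums(Q))), 1e-12)
  expect_true(all(Q[row(Q) != col(Q)] >= 0))
  # expected substitution rate at pi is one per codon per unit length
  expect_equal(-sum(pi * diag(Q)), 1)
  # multi-nucleotide changes are forbidden
  b <- do.call(rbind, strsplit(CODE$codons, ""))
  for (i in sample(61, 8)) for (j in sample(61, 8)) {
    if (sum(b[i, ] != b[j, ]) > 1) expect_equal(Q[i, j], 0)
  }
})

test_that("omega 0 evolution preserves the protein everywhere", {
  root <- random_cds(200, seed = 94)
  fam <- evolve_m0(root, "((a:0.4,b:0.4):0.3,c:0.6);", kappa = 2,
                   omega = 0, seed = 95)
  prots <- translate_cds(fam$leaf_seqs)
  expect_true(all(prots == unname(translate_cds(root))))
  # but synonymous changes did happen
  expect_false(all(fam$leaf_seqs == root))
  # determinism
  fam2 <- evolve_m0(root, "((a:0.4,b:0.4):0.3,c:0.6);", kappa = 2,
                    omega = 0, seed = 95)
  expect_identical(fam$leaf_seqs, fam2$leaf_seqs)
  expect_error(evolve_m0("ATGTAA", "(a:1,b:1);"), "stop")
})

test_that("a long branch converges to the equilibrium frequencies", {
  set.seed(96)
  pi <- f3x4_frequencies(random_cds(3000))
  root <- paste(rep("ATG", 4000), collapse = "")
  fam <- evolve_m0(root, "(a:20);", kappa = 2, omega = 1, pi = pi,
                   seed = 97)
  obs <- as.numeric(count_codons(c(x = fam$leaf_seqs[["a"]])))
  expv <- pi[CODE$codons] * sum(obs)
  chi2 <- sum((obs - expv)^2 / expv)
  expect_lt(chi2, qchisq(0.99, 60))
})

test_that("NG86 classifies differences and corrects distances", {
  s <- random_cds(100, seed = 98)
  k0 <- ng86_kaks(s, s)
  expect_equal(k0$ka, 0)
  expect_equal(k0$ks, 0)

  # one synonymous third-position change: KA stays 0
  cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  i <- which(cods == "AAA")[1]
  if (is.na(i)) { cods[1] <- "AAA"; i <- 1 }
  cods2 <- cods
  cods2[i] <- "AAG"
  k1 <- ng86_kaks(paste(cods, collapse = ""), paste(cods2, collapse = ""))
  expect_equal(k1$ka, 0)
  expect_gt(k1$ks, 0)
  expect_equal(k1$Nd, 0)
  expect_equal(k1$Sd, 1)

  # one nonsynonymous change: KS stays 0
  cods3 <- cods
  cods3[i] <- "GAA"
  k2 <- ng86_kaks(paste(cods, collapse = ""), paste(cods3, collapse = ""))
  expect_equal(k2$ks, 0)
  expect_gt(k2$ka, 0)

  expect_error(ng86_kaks("AAATTT", "AAA"), "length")
})

test_that("measured KA/KS decreases with the simulated omega", {
  root <- random_cds(1500, seed = 99)
  ratios <- vapply(c(0.1, 0.5, 1.0), function(om) {
    fam <- evolve_m0(root, "(a:0.15,b:0.15);", kappa = 2, omega = om,
                     seed = 100)
    ng86_kaks(fam$leaf_seqs[["a"]], fam$leaf_seqs[["b"]])$ratio
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
  expect_lt(ratios[1], 0.2)
})

test_that("the u-shift moves four-fold mass onto U without leaving families", {
  sp <- selected_profile()
  sh <- apply_u_shift(sp, 0.18)
  for (a in names(CODE$families)) {
    fam <- CODE$families[[a]]
    expect_equal(sum(sh$cuf[fam]), 1)
  }
  expect_gt(sh$cuf[["GTT"]], sp$cuf[["GTT"]])
  expect_lt(sh$gc3, sp$gc3)
  # pyrimidine two-fold families untouched
  expect_equal(sh$cuf[["TTC"]], sp$cuf[["TTC"]])
})
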