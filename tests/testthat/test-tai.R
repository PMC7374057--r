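test_that("the pairing table enumerates two decoders per codon", {
  pt <- pairing_table()
  expect_equal(nrow(pt), 122L)
  expect_equal(sort(unique(table(pt$codon))), 2L)
  # Watson-Crick rows use the reverse-complement anticodon
  wc <- pt[pt$class == "WC", ]
  expect_true(all(wc$anticodon ==
                    vapply(wc$codon, function(x) revcomp_oracle(x), "")))
  # one wobble class per codon third base
  expect_setequal(unique(pt$class), c("WC", "AU", "GU", "IC", "IA", "UG"))
})

test_that("absolute adaptiveness follows the pairing arithmetic", {
  # single Phe decoder, wobble disabled: only TTC scores
  s_off <- sij_weights(AU = 1, GU = 1, IC = 1, IA = 1, UG = 1)
  ad <- absolute_adaptiveness(c(GAA = 2), s_off)
  expect_equal(ad$W[ad$codon == "TTC"], 2)
  expect_equal(ad$w[ad$codon == "TTC"], 1)
  expect_equal(ad$W[ad$codon == "TTT"], 0)
  expect_true(ad$substituted[ad$codon == "TTT"])

  # allow the G:U wobble at half efficiency
  s_gu <- sij_weights(AU = 1, GU = 0.5, IC = 1, IA = 1, UG = 1)
  ad2 <- absolute_adaptiveness(c(GAA = 2), s_gu)
  expect_equal(ad2$W[ad2$codon == "TTT"], 1)
  expect_equal(ad2$w[ad2$codon == "TTT"], 0.5)

  expect_error(absolute_adaptiveness(c(GAA = 0)), "empty|decodes")
  expect_error(absolute_adaptiveness(c(GAAA = 1)), "triplets")
})

test_that("adaptiveness matches a brute-force anticodon-centric oracle", {
  set.seed(31)
  acs <- sample(revcomp_oracle(CODE$codons), 40)
  pool <- setNames(sample(1:6, 40, TRUE), acs)
  s <- sij_weights(AU = 0.1, GU = 0.4, IC = 0.3, IA = 0.95, UG = 0.7)
  ad <- absolute_adaptiveness(pool, s)

  # oracle: enumerate, per anticodon, the codons it may decode
  W <- setNames(rep(0, 61), CODE$codons)
  for (ac in names(pool)) {
    stem12 <- revcomp_oracle(substr(ac, 2, 3))   # codon positions 1-2
    b34 <- substr(ac, 1, 1)
    reads <- switch(b34,
      A = c(T = 1 - s[["AU"]], C = 1 - s[["IC"]], A = 1 - s[["IA"]]),
      G = c(C = 1, T = 1 - s[["GU"]]),
      T = c(A = 1, G = 1 - s[["UG"]]),
      C = c(G = 1))
    for (third in names(reads)) {
      cod <- paste0(stem12, third)
      if (cod %in% CODE$codons) W[cod] <- W[cod] + reads[[third]] * pool[[ac]]
    }
  }
  expect_equal(setNames(ad$W, ad$codon), W)
})

test_that("w never decreases when a pairing anticodon gains copies", {
  s <- sij_weights()
  pool <- c(GAA = 2, TAC = 1, CAT = 3, GGT = 2)
  ad <- absolute_adaptiveness(pool, s)
  pool2 <- pool; pool2[["GAA"]] <- 5
  ad2 <- absolute_adaptiveness(pool2, s)
  # TTC is decoded by GAA: its absolute adaptiveness must rise
  expect_gt(ad2$W[ad2$codon == "TTC"], ad$W[ad$codon == "TTC"])
})

test_that("tAI is the geometric mean of w with multiplicity", {
  ad1 <- make_adapt(setNames(rep(1, 61), CODE$codons))
  set.seed(32)
  cnt <- count_codons(c(g = random_cds(150)))
  expect_equal(gene_tai(cnt, ad1), 1)

  ad <- make_adapt(c(AAA = 0.25, GGG = 1))
  expect_equal(gene_tai(c(AAA = 1, GGG = 1), ad), 0.5)

  # log-domain brute force on a random gene with random w
  w <- setNames(runif(61, 0.05, 1), CODE$codons)
  adw <- make_adapt(w)
  x <- as.numeric(cnt); names(x) <- CODE$codons
  oracle <- exp(sum(x * log(w)) / sum(x))
  expect_equal(gene_tai(cnt, adw), oracle)

  # invariance under gene duplication
  s1 <- random_cds(90)
  expect_equal(gene_tai(count_codons(c(g = s1)), adw),
               gene_tai(count_codons(c(g = paste0(s1, s1))), adw))
})

test_that("m-tAI matches the tAI of the realized modal sequence", {
  sp <- selected_profile()
  pool <- derive_trna_pool(sp, 120)
  ad <- absolute_adaptiveness(pool)
  m1 <- modal_tai(sp, ad)
  m2 <- gene_tai(count_codons(c(m = modal_sequence(sp))), ad)
  expect_lt(abs(m1 - m2), 1e-3)

  # uniform w: m-tAI is exactly 1
  expect_equal(modal_tai(sp, make_adapt(setNames(rep(1, 61), CODE$codons))),
               1)

  # shifting Phe usage toward the better-adapted codon raises m-tAI
  w <- setNames(ad$w, ad$codon)
  phe <- CODE$families[["F"]]
  better <- phe[which.max(w[phe])]
  worse <- phe[which.min(w[phe])]
  shifted <- sp$cuf
  shifted[better] <- shifted[better] + 0.1
  shifted[worse] <- shifted[worse] - 0.1
  sp2 <- profile_from_cuf(shifted[!is.na(shifted)], sp$aa_freq)
  expect_gt(modal_tai(sp2, ad), m1)
})

test_that("DCBS is 1 for factorizable usage and >= 1 always", {
  # equal AAA/AAG counts factorize into positional frequencies exactly
  expect_equal(gene_dcbs(c(AAA = 5, AAG = 5)), 1)
  set.seed(33)
  for (i in 1:10) {
    d <- gene_dcbs(count_codons(c(g = random_cds(200))))
    expect_gte(d, 1)
  }

  # independent two-pass recomputation
  cnt <- count_codons(c(g = random_cds(300)))
  x <- as.numeric(cnt); names(x) <- CODE$codons
  n <- sum(x)
  f <- x / n
  posf <- lapply(1:3, function(p) {
    tapply(x, substr(CODE$codons, p, p), sum) / n
  })
  d_oracle <- 0
  for (cod in CODE$codons[x > 0]) {
    e <- posf[[1]][[substr(cod, 1, 1)]] * posf[[2]][[substr(cod, 2, 2)]] *
      posf[[3]][[substr(cod, 3, 3)]]
    r <- f[[cod]] / e
    d_oracle <- d_oracle + x[[cod]] * max(r, 1 / r)
  }
  expect_equal(gene_dcbs(cnt), d_oracle / n)
})

test_that("Sij training is reproducible and improves on its starts", {
  g <- generate_genome(genome_sim_config(
    data.frame(set = c("lo", "hi"), size = c(40, 40), mix = c(0.1, 0.9)),
    seed = 14))
  cnt <- count_codons(g$sequences)
  pool <- derive_trna_pool(selected_profile(), 120)
  f1 <- train_sij(cnt, pool, restarts = 3, seed = 7)
  f2 <- train_sij(cnt, pool, restarts = 3, seed = 7)
  expect_identical(unclass(f1$s), unclass(f2$s))
  expect_identical(f1$rho, f2$rho)
  expect_true(all(f1$rho >= f1$start_objectives - 1e-12))
  expect_true(all(unclass(f1$s) >= 0 & unclass(f1$s) <= 1))

  # identical genes: DCBS has zero variance
  same <- count_codons(setNames(rep("AAAGAACTG", 60), paste0("g", 1:60)))
  expect_error(train_sij(same, pool, restarts = 2, seed = 1),
               "zero variance")
})

test_that("derived tRNA pools are consistent with the planted preference", {
  sp <- selected_profile()
  pool <- derive_trna_pool(sp, 120)
  expect_true(all(pool >= 1))
  expect_lte(abs(sum(pool) - 120), 10)   # coverage bumps only

  # Phe: G34 anticodon (GAA) carries the preference for TTC
  expect_gt(pool[["GAA"]], 2)

  # planted-preference closure: w under the true penalties ranks like CUF
  ad <- absolute_adaptiveness(pool, sij_weights())
  w <- setNames(ad$w, ad$codon)
  deg <- CODE$degeneracy[AA_OF] > 1
  rho <- cor(w[deg], sp$cuf[CODE$codons][deg], method = "spearman")
  expect_gte(rho, 0.9)

  # uniform profile gives near-uniform copies within a family's decoders
  pu <- derive_trna_pool(uniform_profile(), 120)
  val_acs <- intersect(c("AAC", "GAC", "TAC", "CAC"), names(pu))
  expect_lte(diff(range(pu[val_acs])), 1)
})
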