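test_that("codon counting follows the code table, skip and frame rules", {
  cc <- count_codons(c(g1 = "ATGAAATAA", g2 = "ATGAANGGG"))
  expect_equal(unname(cc["g1", c("ATG", "AAA")]), c(1L, 1L))
  expect_equal(sum(cc["g1", ]), 2L)              # stop excluded
  expect_equal(unname(cc["g2", c("ATG", "GGG")]), c(1L, 1L))
  expect_equal(sum(cc["g2", ]), 2L)              # ambiguous AAN skipped
  expect_equal(unname(attr(cc, "skipped")["g2"]), 1L)

  expect_error(count_codons(c(bad = "ATGAA")), "bad")
  expect_warning(cc2 <- count_codons(c(g = "ATGAA"), frame = "trim"),
                 "trimming")
  expect_equal(sum(cc2), 1L)
  expect_equal(nrow(count_codons(character(0))), 0L)

  # RNA input and lowercase accepted
  expect_equal(sum(count_codons(c(g = "auguuu"))), 2L)
})

test_that("counting is additive and matches a brute-force scan", {
  set.seed(101)
  seqs <- setNames(vapply(1:100, function(i) random_cds(300), ""),
                   paste0("g", 1:100))
  cc <- count_codons(seqs)
  oracle <- vapply(seqs, oracle_sense_codon_count, integer(1))
  expect_equal(unname(rowSums(cc)), unname(oracle))

  a <- seqs[[1]]; b <- seqs[[2]]
  cat_counts <- count_codons(c(x = paste0(a, b)))
  expect_equal(as.numeric(cat_counts),
               as.numeric(count_codons(c(x = a)) + count_codons(c(x = b))))
})

test_that("CUF, RSCU, aa_freq and GC3 follow their definitions", {
  p <- usage_profile(c(AAA = 3, AAG = 1))
  expect_equal(unname(p$cuf[c("AAA", "AAG")]), c(0.75, 0.25))
  expect_equal(unname(p$rscu[c("AAA", "AAG")]), c(1.5, 0.5))

  # uniform counts: cuf = 1/k per family, rscu = 1, gc3 by enumeration
  u <- setNames(rep(1, 61), CODE$codons)
  pu <- usage_profile(u)
  k <- CODE$degeneracy[AA_OF]
  expect_equal(unname(pu$cuf), unname(1 / k))
  expect_equal(unname(pu$rscu), rep(1, 61))
  gc3_oracle <- mean(substr(CODE$codons, 3, 3) %in% c("G", "C"))
  expect_equal(pu$gc3, gc3_oracle)
  expect_equal(sum(pu$aa_freq), 1)

  # absent family undefined, others normalized
  x <- u
  x[CODE$families[["H"]]] <- 0
  ph <- usage_profile(x)
  expect_true(all(is.na(ph$cuf[CODE$families[["H"]]])))
  expect_false(anyNA(ph$cuf[CODE$families[["K"]]]))
  for (a in setdiff(names(CODE$families), "H")) {
    expect_equal(sum(ph$cuf[CODE$families[[a]]]), 1)
  }

  expect_error(usage_profile(setNames(rep(0, 61), CODE$codons)),
               "no sense codons")

  # random gene: rscu equals k * count / family total, per-family loop
  set.seed(5)
  cnt <- as.numeric(count_codons(c(g = random_cds(300))))
  names(cnt) <- CODE$codons
  pr <- usage_profile(cnt)
  for (a in names(CODE$families)) {
    fam <- CODE$families[[a]]
    tot <- sum(cnt[fam])
    if (tot == 0) next
    expect_equal(unname(pr$rscu[fam]), unname(length(fam) * cnt[fam] / tot))
  }

  # GC3 equals 1 - AT3 computed independently
  at3 <- sum(cnt[substr(CODE$codons, 3, 3) %in% c("A", "T")]) / sum(cnt)
  expect_equal(pr$gc3, 1 - at3)
})

test_that("zero-filled RSCU matrix is the CA input convention", {
  cc <- count_codons(c(g1 = "AAAAAGAAA", g2 = "TTTTTC"))
  rm <- rscu_matrix(cc)
  expect_equal(unname(rm["g1", c("AAA", "AAG")]), c(4 / 3, 2 / 3))
  expect_equal(unname(rm["g1", "TTT"]), 0)    # absent family zero-filled
  expect_true(all(rm >= 0))
})

test_that("Wright's Nc hits the analytic extremes and the oracle", {
  u <- setNames(rep(1e6, 61), CODE$codons)
  expect_lt(abs(suppressWarnings(effective_number_of_codons(u)) - 61), 1e-3)

  one <- setNames(rep(0, 61), CODE$codons)
  for (fam in CODE$families) one[fam[1]] <- 100
  expect_equal(effective_number_of_codons(one), 20)

  # independent reimplementation of F per amino acid
  oracle_nc <- function(x) {
    fbar <- c()
    kk <- c()
    for (a in names(CODE$families)) {
      fam <- CODE$families[[a]]
      if (length(fam) < 2) next
      n <- sum(x[fam])
      if (n < 2) next
      p <- x[fam] / n
      fbar <- c(fbar, (n * sum(p^2) - 1) / (n - 1))
      kk <- c(kk, length(fam))
    }
    means <- tapply(fbar, kk, mean)
    2 + 9 / means[["2"]] + 1 / means[["3"]] + 5 / means[["4"]] +
      3 / means[["6"]]
  }
  set.seed(42)
  for (i in 1:50) {
    cnt <- as.numeric(count_codons(c(g = random_cds(400))))
    names(cnt) <- CODE$codons
    fam_n <- tapply(cnt, AA_OF, sum)
    # oracle requires every degeneracy class computable
    if (any(fam_n[c("I")] < 2)) next
    expect_equal(suppressWarnings(effective_number_of_codons(cnt)),
                 unname(oracle_nc(cnt)))
  }
})

test_that("Nc is count-scale invariant and decreases as usage concentrates", {
  set.seed(9)
  cnt <- as.numeric(count_codons(c(g = random_cds(500)))) * 100
  names(cnt) <- CODE$codons
  nc1 <- suppressWarnings(effective_number_of_codons(cnt))
  nc10 <- suppressWarnings(effective_number_of_codons(cnt * 10))
  expect_lt(abs(nc1 - nc10), 0.05)

  # interpolate from uniform usage to one codon per aa
  u <- setNames(rep(1e5, 61), CODE$codons)
  one <- setNames(rep(0, 61), CODE$codons)
  for (fam in CODE$families) one[fam[1]] <- 1e5 * length(fam)
  ncs <- vapply(seq(0, 1, 0.25), function(t) {
    suppressWarnings(effective_number_of_codons((1 - t) * u + t * one))
  }, numeric(1))
  expect_true(all(diff(ncs) < 0))
})

test_that("the genetic code table has the standard structure", {
  expect_equal(length(CODE$codons), 61L)
  expect_equal(CODE$stops, c("TAA", "TAG", "TGA"))
  census <- table(CODE$degeneracy)
  expect_equal(as.integer(census[c("1", "2", "3", "4", "6")]),
               c(2L, 9L, 1L, 5L, 3L))
  expect_equal(sort(unname(unlist(CODE$families))), CODE$codons)
})
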