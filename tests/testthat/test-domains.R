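test_that("HEP/LEP selection slices the abundance quantiles", {
  ab <- setNames(1:100, paste0("g", 1:100))
  hl <- select_hep_lep(ab, names(ab), hep_q = 0.9, lep_q = 0.1)
  expect_equal(sort(hl$hep), sort(paste0("g", 91:100)))
  expect_equal(sort(hl$lep), sort(paste0("g", 1:10)))
  expect_length(intersect(hl$hep, hl$lep), 0)

  expect_error(select_hep_lep(setNames(rep(2, 30), paste0("g", 1:30)),
                              paste0("g", 1:30)), "degenerate")
  expect_error(select_hep_lep(ab, names(ab), hep_q = 0.2, lep_q = 0.5),
               "lep_q < hep_q")

  # log-normal abundances against a sort-and-slice oracle
  set.seed(61)
  ab2 <- setNames(rlnorm(1000, 2, 1), paste0("p", 1:1000))
  hl2 <- select_hep_lep(ab2, names(ab2))
  srt <- sort(ab2)
  expect_true(all(ab2[hl2$lep] <= srt[[100]]))
  expect_true(all(ab2[hl2$hep] >= srt[[901]]))
  expect_gte(length(hl2$hep), 100)
  expect_gte(length(hl2$lep), 100)

  # genes without abundance are excluded and counted
  hl3 <- select_hep_lep(ab, c(names(ab), paste0("x", 1:7)))
  expect_equal(hl3$n_missing, 7)
})

test_that("backthreading maps codons onto alignment columns", {
  aln <- c(m1 = "MKL", m2 = "MKL")
  cds <- c(m1 = "ATGAAACTG", m2 = "ATGAAATTATAA")  # terminal stop ok
  bt <- backthread(aln, cds)
  expect_equal(unname(bt$codons["m1", ]), c("ATG", "AAA", "CTG"))
  expect_equal(unname(bt$codons["m2", ]), c("ATG", "AAA", "TTA"))

  # gap bookkeeping: member 2 skips the gapped column
  aln2 <- c(m1 = "MKL", m2 = "M-L")
  cds2 <- c(m1 = "ATGAAACTG", m2 = "ATGCTG")
  bt2 <- backthread(aln2, cds2)
  expect_equal(unname(bt2$codons["m2", ]), c("ATG", "---", "CTG"))

  expect_error(backthread(c(m1 = "MKL"), c(m1 = "ATGAAAGTG")),
               "mismatch")
  expect_error(backthread(c(m1 = "MKL"), c(m1 = "ATGAAA")), "codons|frame")
})

test_that("column classification follows the conservation rules", {
  aln <- c(a = "AAAA", b = "AAAB", c = "AABB", d = "AABC")
  # columns: AAAA (conserved), AAAA? build per-column cases explicitly
  rows <- c(a = "AAAA", b = "AABA", c = "AABB", d = "AABB")
  # col1 AAAA conserved; col2 AAAA conserved; col3 ABBB intermediate;
  # col4 AABB variable (max prop 0.5)
  cds <- vapply(rows, function(s) {
    paste(c(A = "GCT", B = "TGG")[strsplit(s, "")[[1]]], collapse = "")
  }, "")
  # recode: use real aa letters A and W
  rows <- gsub("B", "W", rows)
  bt <- classify_columns(backthread(rows, cds))
  expect_equal(bt$column_class,
               c("conserved", "conserved", "intermediate", "variable"))

  # a gap disqualifies conservation; gaps leave the vr denominator
  rows2 <- c(a = "A-AW", b = "AAAW", c = "A-WA", d = "AWWA")
  cds2 <- vapply(gsub("-", "", rows2), function(s) {
    paste(c(A = "GCT", W = "TGG")[strsplit(s, "")[[1]]], collapse = "")
  }, "")
  names(cds2) <- names(rows2)
  bt2 <- classify_columns(backthread(rows2, cds2))
  expect_equal(bt2$column_class[1], "conserved")     # AAAA
  expect_equal(bt2$column_class[2], "variable")      # -,A,-,W: 1/2 each
  expect_equal(bt2$column_class[3], "variable")      # A,A,W,W among 4
  expect_equal(bt2$column_class[4], "variable")      # W,W,A,A
})

test_that("domain extraction concatenates the reference codons", {
  rows <- c(r = "MKLFW", s = "MKIYW", t = "MKVAW")
  # col1 M conserved, col2 K conserved, col3 L/I/V variable,
  # col4 F/Y/A variable, col5 W conserved
  cds <- c(r = "ATGAAACTGTTTTGG", s = "ATGAAAATTTATTGG",
           t = "ATGAAAGTTGCTTGG")
  bt <- classify_columns(backthread(rows, cds))
  expect_equal(extract_domains(bt, "cr"), "ATGAAATGG")
  expect_equal(extract_domains(bt, "vr"), "CTGTTT")
  expect_equal(conservation_percent(bt), 60)

  # fully conserved family: vr empty, cr is the whole reference
  rows2 <- c(r = "MKL", s = "MKL")
  cds2 <- c(r = "ATGAAACTG", s = "ATGAAATTA")
  bt2 <- classify_columns(backthread(rows2, cds2))
  expect_equal(extract_domains(bt2, "cr"), "ATGAAACTG")
  expect_warning(v <- extract_domains(bt2, "vr"), "no vr")
  expect_equal(v, "")
  expect_equal(conservation_percent(bt2), 100)

  # every column gets exactly one class
  expect_equal(sort(unique(bt$column_class)),
               sort(intersect(c("conserved", "variable", "intermediate"),
                              bt$column_class)))
})

test_that("simulated families behave: omega 0 keeps cr everything", {
  root <- random_cds(150, seed = 62)
  fam <- evolve_m0(root, "((a:0.4,b:0.4):0.2,(c:0.4,d:0.4):0.2);",
                   kappa = 2, omega = 0, seed = 63)
  prots <- translate_cds(fam$leaf_seqs)
  bt <- classify_columns(backthread(prots, fam$leaf_seqs))
  expect_true(all(bt$column_class == "conserved"))
  expect_equal(extract_domains(bt, "cr"), unname(fam$leaf_seqs[1]))
  expect_equal(conservation_percent(bt), 100)

  # round trip: translating the backthreaded codons reproduces the rows
  for (m in rownames(bt$aa)) {
    cods <- bt$codons[m, bt$codons[m, ] != "---"]
    expect_equal(unname(translate_cds(paste(cods, collapse = ""))),
                 paste(bt$aa[m, bt$aa[m, ] != "-"], collapse = ""))
  }
})

test_that("conservation percent decreases with omega", {
  root <- random_cds(200, seed = 64)
  tree <- "((a:0.5,b:0.5):0.25,(c:0.5,d:0.5):0.25);"
  cons <- vapply(c(0.05, 0.3, 1.0), function(om) {
    fam <- evolve_m0(root, tree, kappa = 2, omega = om, seed = 65)
    prots <- translate_cds(fam$leaf_seqs)
    conservation_percent(classify_columns(backthread(prots, fam$leaf_seqs)))
  }, numeric(1))
  expect_true(all(diff(cons) < 0))
})
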