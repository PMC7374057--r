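#' Per-codon CUF difference between two gene sets
#'
#' Computes delta(c) = CUF1(c) - CUF2(c) for every codon whose family is
#' defined in both profiles. Within each shared family the deltas sum to
#' zero by construction. Families undefined in either profile are excluded
#' and listed.
#'
#' @param profile1,profile2 [usage_profile()] objects (set 1 minus set 2).
#' @param code A [genetic_code()].
#' @return Object of class `bias_profile`: list with `delta` (named over
#'   defined codons), `excluded_families`, and the two GC3 values.
#' @export
delta_cuf <- function(profile1, profile2, code = genetic_code()) {
  aa <- codon_aa(code, code$codons)
  def1 <- !is.na(profile1$cuf)
  def2 <- !is.na(profile2$cuf)
  shared <- def1 & def2
  if (!any(shared)) stop("profiles share no defined codon families")
  excluded <- sort(unique(aa[!shared]))
  delta <- profile1$cuf[shared] - profile2$cuf[shared]
  structure(
    list(delta = delta, excluded_families = excluded,
         gc3_1 = profile1$gc3, gc3_2 = profile2$gc3),
    class = "bias_profile"
  )
}

#' @export
print.bias_profile <- function(x, ...) {
  cat("CUF difference profile over", length(x$delta), "codons\n")
  if (length(x$excluded_families)) {
    cat("  excluded families:", paste(x$excluded_families, collapse = ", "),
        "\n")
  }
  top <- sort(abs(x$delta), decreasing = TRUE)[1:5]
  cat("  largest |delta|:",
      paste(sprintf("%s %+0.3f", names(top), x$delta[names(top)]),
            collapse = ", "), "\n")
  invisible(x)
}

# codons eligible for the C-bias test: C-ending members of the
# pyrimidine-ending two-fold families Asp, Phe, His, Asn, Tyr plus the
# three-fold Ile codon; Cys (TGC) is excluded because no consistent C bias
# with ancestry is observed there
c_bias_codons <- function() c("GAC", "TTC", "CAC", "AAC", "TAC", "ATC")

# codons eligible for the U-bias test: U-ending codons of the four-fold
# families (Val, Thr, Pro, Ala, Gly) and of the four-fold boxes of the
# six-fold amino acids (Ser TCN, Leu CTN, Arg CGN)
u_bias_codons <- function() c("GTT", "ACT", "CCT", "GCT", "GGT",
                              "TCT", "CTT", "CGT")

# one-sample one-sided t test with explicit handling of the zero-variance
# degenerate case (constant deltas)
one_sided_t <- function(x, alternative = "greater") {
  n <- length(x)
  m <- mean(x)
  s <- stats::sd(x)
  if (s == 0 || is.na(s)) {
    tval <- if (m == 0) 0 else sign(m) * Inf
    p <- if (m == 0) 0.5 else if (m > 0) 0 else 1
    if (alternative == "less") p <- 1 - p
    return(list(statistic = tval, p.value = p, estimate = m, df = n - 1,
                degenerate = TRUE))
  }
  tval <- m / (s / sqrt(n))
  p <- stats::pt(tval, df = n - 1,
                 lower.tail = (alternative == "less"))
  list(statistic = tval, p.value = p, estimate = m, df = n - 1,
       degenerate = FALSE)
}

bias_test <- function(delta, eligible, alternative, label) {
  if (inherits(delta, "bias_profile")) delta <- delta$delta
  d <- delta[intersect(eligible, names(delta))]
  d <- d[!is.na(d)]
  if (length(d) < 3) {
    stop("fewer than 3 eligible codons with defined delta for the ",
         label, " test")
  }
  res <- one_sided_t(d, alternative)
  structure(
    list(bias = label, statistic = res$statistic, p.value = res$p.value,
         mean_delta = res$estimate, df = res$df, codons = names(d),
         degenerate = res$degenerate, alternative = alternative),
    class = "bias_test"
  )
}

#' C-bias and U-bias tests
#'
#' One-sample t tests of the per-codon CUF deltas against zero, one-sided
#' towards enrichment (delta > 0), over the codons diagnostic of
#' translational selection at the third position: `c_bias_test()` uses the
#' C-ending codons of the pyrimidine-ending 2-fold families (Asp GAC, Phe
#' UUC, His CAC, Asn AAC, Tyr UAC) and 3-fold Ile AUC, excluding Cys;
#' `u_bias_test()` uses the U-ending codons of the 4-fold families and of
#' the 4-fold boxes of the 6-fold amino acids (Ser, Leu, Arg). A constant
#' delta vector is reported as an infinite-t degenerate case (p = 0 for a
#' positive mean) rather than NaN.
#'
#' @param delta A [delta_cuf()] result (or plain named delta vector).
#' @param alternative `"greater"` (default: enrichment in set 1) or
#'   `"less"`.
#' @return Object of class `bias_test`: statistic, p.value, mean_delta,
#'   df, codons used, and a `degenerate` flag.
#' @export
c_bias_test <- function(delta, alternative = c("greater", "less")) {
  bias_test(delta, c_bias_codons(), match.arg(alternative), "C")
}

#' @rdname c_bias_test
#' @export
u_bias_test <- function(delta, alternative = c("greater", "less")) {
  bias_test(delta, u_bias_codons(), match.arg(alternative), "U")
}

#' Cross-species bias test
#'
#' Aggregated flavor of the bias tests: takes one delta vector per species
#' (rows of a matrix or a list of [delta_cuf()] results), reduces each to
#' its mean eligible delta, and t-tests the species means against zero.
#'
#' @param deltas Matrix (species x codons) or list of `bias_profile`s.
#' @param bias `"C"` or `"U"`.
#' @param alternative As in [c_bias_test()].
#' @return A `bias_test` object over species means.
#' @export
species_bias_test <- function(deltas, bias = c("C", "U"),
                              alternative = c("greater", "less")) {
  bias <- match.arg(bias)
  alternative <- match.arg(alternative)
  eligible <- if (bias == "C") c_bias_codons() else u_bias_codons()
  if (is.list(deltas) && !is.data.frame(deltas)) {
    means <- vapply(deltas, function(d) {
      if (inherits(d, "bias_profile")) d <- d$delta
      mean(d[intersect(eligible, names(d))], na.rm = TRUE)
    }, numeric(1))
  } else {
    means <- rowMeans(deltas[, intersect(eligible, colnames(deltas)),
                             drop = FALSE], na.rm = TRUE)
  }
  if (length(means) < 3) stop("need at least 3 species")
  res <- one_sided_t(means, alternative)
  structure(
    list(bias = bias, statistic = res$statistic, p.value = res$p.value,
         mean_delta = res$estimate, df = res$df,
         codons = eligible, degenerate = res$degenerate,
         alternative = alternative, mode = "species"),
    class = "bias_test"
  )
}

#' @export
print.bias_test <- function(x, ...) {
  cat(x$bias, "-bias test (one-sided ", x$alternative, "): mean delta = ",
      sprintf("%+0.4f", x$mean_delta), ", t = ",
      format(round(x$statistic, 3)), ", df = ", x$df,
      ", p = ", format.pval(x$p.value, digits = 3), "\n", sep = "")
  if (x$degenerate) cat("  (constant deltas: degenerate t)\n")
  invisible(x)
}

#' Classify a genome's codon-usage diversity group
#'
#' Assigns one of the groups A-D from the global GC content and the GC3
#' of the singleton, core and PHE gene sets:
#' A: very low GC (< 0.36) with GC3 singletons > core > PHE;
#' B: biphasic, GC3(core) exceeding both GC3(PHE) and GC3(singletons) by at
#' least `b_margin`; C: GC3 PHE > core > singletons; D: high GC
#' (>= `d_gc_min`) with GC3 core >= PHE > singletons. Rules are evaluated
#' in that order; an unclassifiable genome returns `"none"` with the
#' evidence retained.
#'
#' @param gc_total Global GC fraction of the coding regions.
#' @param gc3_singletons,gc3_core,gc3_phe GC3 of the three gene sets
#'   (core = the most ancestral pooled core set by default).
#' @param b_margin Margin (GC3 fraction) for the biphasic group-B call;
#'   default 0.03.
#' @param d_gc_min Lower global-GC bound for group D; default 0.60.
#' @return Object of class `group_call`: list with `group` and `evidence`.
#' @export
classify_group <- function(gc_total, gc3_singletons, gc3_core, gc3_phe,
                           b_margin = 0.03, d_gc_min = 0.60) {
  stopifnot(is.finite(gc_total), is.finite(gc3_singletons),
            is.finite(gc3_core), is.finite(gc3_phe))
  group <- "none"
  if (gc_total < 0.36 && gc3_singletons > gc3_core && gc3_core > gc3_phe) {
    group <- "A"
  } else if (gc3_core - max(gc3_phe, gc3_singletons) >= b_margin) {
    group <- "B"
  } else if (gc3_phe > gc3_core && gc3_core > gc3_singletons) {
    group <- "C"
  } else if (gc_total >= d_gc_min && gc3_core >= gc3_phe &&
             gc3_phe > gc3_singletons) {
    group <- "D"
  }
  structure(
    list(group = group,
         evidence = list(gc_total = gc_total,
                         gc3 = c(singletons = gc3_singletons,
                                 core = gc3_core, phe = gc3_phe),
                         b_margin = b_margin, d_gc_min = d_gc_min)),
    class = "group_call"
  )
}

#' @export
print.group_call <- function(x, ...) {
  cat("Codon usage diversity group:", x$group, "\n")
  cat("  global GC ", sprintf("%.3f", x$evidence$gc_total), "; GC3 ",
      paste(sprintf("%s %.3f", names(x$evidence$gc3), x$evidence$gc3),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}
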