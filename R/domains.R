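#' Select highly and lowly expressed gene subsets (HEP / LEP)
#'
#' Splits the core genes with abundance data into a highly expressed
#' subset (abundance at or above the `hep_q` quantile) and a lowly
#' expressed subset (at or below the `lep_q` quantile), disjoint by
#' construction.
#'
#' @param abundance Named positive numeric vector (protein id ->
#'   abundance, ppm-like scale) or data frame with columns `protein` and
#'   `abundance`.
#' @param core_genes Character vector of gene ids forming the core set.
#' @param hep_q,lep_q Upper and lower quantiles, 0 < lep_q < hep_q < 1;
#'   defaults 0.9 and 0.1.
#' @return List with `hep`, `lep` (gene id vectors), `n_missing` (core
#'   genes without abundance data) and the two quantile cutoffs.
#' @export
select_hep_lep <- function(abundance, core_genes, hep_q = 0.9,
                           lep_q = 0.1) {
  if (is.data.frame(abundance)) {
    abundance <- stats::setNames(abundance$abundance, abundance$protein)
  }
  if (!(lep_q > 0 && hep_q < 1 && lep_q < hep_q)) {
    stop("need 0 < lep_q < hep_q < 1")
  }
  if (any(abundance <= 0)) stop("abundances must be strictly positive")
  x <- abundance[intersect(core_genes, names(abundance))]
  n_missing <- length(core_genes) - length(x)
  if (length(x) < 2) stop("fewer than 2 core genes with abundance data")
  if (length(x) < 20) {
    warning("only ", length(x), " core genes with abundance data")
  }
  if (max(x) == min(x)) stop("degenerate abundance distribution")
  hq <- stats::quantile(x, hep_q, names = FALSE)
  lq <- stats::quantile(x, lep_q, names = FALSE)
  hep <- names(x)[x >= hq]
  lep <- names(x)[x <= lq]
  both <- intersect(hep, lep)
  if (length(both)) stop("degenerate abundance distribution: HEP and LEP overlap")
  list(hep = hep, lep = lep, n_missing = n_missing,
       cutoffs = c(lep = lq, hep = hq))
}

#' Back-thread codons onto an amino-acid alignment
#'
#' Builds a codon alignment from an aligned set of protein sequences and
#' the corresponding unaligned coding sequences: each amino-acid column
#' carries, per member, either the codon that encodes the residue or a
#' codon gap. A single terminal stop codon on a CDS is tolerated and
#' dropped. The translation of each CDS must reproduce its ungapped
#' aligned row exactly.
#'
#' @param aa_alignment Named character vector of aligned amino-acid rows
#'   (gaps as `-`), all of equal length.
#' @param cds Named character vector of the members' unaligned in-frame
#'   coding sequences.
#' @param reference Id of the reference member (defaults to the first row)
#'   whose codons [extract_domains()] will concatenate.
#' @param code A [genetic_code()].
#' @return Object of class `codon_alignment`: list with `aa` (members x
#'   columns character matrix), `codons` (same shape, `---` for gaps),
#'   `members`, `reference`, and `column_class` (filled by
#'   [classify_columns()], initially NULL).
#' @export
backthread <- function(aa_alignment, cds, reference = NULL,
                       code = genetic_code()) {
  if (length(aa_alignment) < 1) stop("empty alignment")
  members <- names(aa_alignment)
  if (is.null(members) || any(!members %in% names(cds))) {
    stop("alignment rows and CDS must share names")
  }
  width <- unique(nchar(aa_alignment))
  if (length(width) != 1) stop("aligned rows differ in length")
  aa_mat <- t(vapply(aa_alignment, function(s) strsplit(s, "")[[1]],
                     character(width)))
  cod_mat <- matrix("---", nrow = length(members), ncol = width,
                    dimnames = list(members, NULL))
  for (m in members) {
    s <- normalize_dna(cds[[m]])
    if (nchar(s) %% 3L != 0L) {
      stop("CDS of '", m, "' is not in frame")
    }
    cods <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
    if (length(cods) && code$codon_to_aa[cods[length(cods)]] == "*") {
      cods <- cods[-length(cods)]
    }
    res_cols <- which(aa_mat[m, ] != "-")
    if (length(cods) != length(res_cols)) {
      stop("CDS of '", m, "' has ", length(cods),
           " codons but its aligned row has ", length(res_cols),
           " residues")
    }
    trans <- code$codon_to_aa[cods]
    mism <- which(trans != aa_mat[m, res_cols])
    if (length(mism)) {
      stop("translation mismatch for '", m, "' at alignment column ",
           res_cols[mism[1]], " (", trans[mism[1]], " vs ",
           aa_mat[m, res_cols[mism[1]]], ")")
    }
    cod_mat[m, res_cols] <- cods
  }
  structure(
    list(aa = aa_mat, codons = cod_mat, members = members,
         reference = if (is.null(reference)) members[1] else reference,
         column_class = NULL),
    class = "codon_alignment"
  )
}

#' Classify alignment columns as conserved / variable / intermediate
#'
#' A column is conserved when a single amino acid occupies every row (a
#' column containing any gap is never conserved); variable when no amino
#' acid reaches a proportion above 0.5 among the non-gap residues; and
#' intermediate otherwise.
#'
#' @param aln A [backthread()] codon alignment with at least 2 members.
#' @return The alignment with `column_class` filled (character vector over
#'   columns with values `conserved`, `variable`, `intermediate`).
#' @export
classify_columns <- function(aln) {
  if (nrow(aln$aa) < 2) stop("need at least 2 members")
  cls <- apply(aln$aa, 2, function(col) {
    nongap <- col[col != "-"]
    if (length(nongap) == 0) return("intermediate")
    if (length(nongap) == length(col) && length(unique(nongap)) == 1) {
      return("conserved")
    }
    if (max(table(nongap)) / length(nongap) <= 0.5) return("variable")
    "intermediate"
  })
  aln$column_class <- as.character(cls)
  aln
}

#' Extract the concatenated conserved or variable codon domain
#'
#' Concatenates, in column order, the reference member's codons at the
#' columns of the requested class, skipping reference gaps. The output is
#' a plain coding sequence ready for codon counting and modal-usage
#' estimation (the HEP_cr / HEP_vr / LEP_cr / LEP_vr building block).
#'
#' @param aln A classified [codon_alignment] (see [classify_columns()]).
#' @param which `"cr"` (conserved) or `"vr"` (variable).
#' @return A single nucleotide string; empty (with a warning) when no
#'   column qualifies.
#' @export
extract_domains <- function(aln, which = c("cr", "vr")) {
  which <- match.arg(which)
  if (is.null(aln$column_class)) aln <- classify_columns(aln)
  target <- if (which == "cr") "conserved" else "variable"
  cols <- base::which(aln$column_class == target)
  ref <- aln$codons[aln$reference, cols]
  ref <- ref[ref != "---"]
  if (!length(ref)) {
    warning("no ", which, " codons for reference '", aln$reference, "'")
    return("")
  }
  paste(ref, collapse = "")
}

#' Percent amino-acid sequence conservation
#'
#' Share of fully conserved columns among the columns where the reference
#' member has a residue, on a 0-100 scale. `method = "pairwise"` instead
#' reports the mean pairwise identity over non-gap positions.
#'
#' @param aln A classified [codon_alignment].
#' @param method `"conserved_columns"` (default) or `"pairwise"`.
#' @return A percentage in [0, 100].
#' @export
conservation_percent <- function(aln,
                                 method = c("conserved_columns",
                                            "pairwise")) {
  method <- match.arg(method)
  if (is.null(aln$column_class)) aln <- classify_columns(aln)
  if (method == "conserved_columns") {
    ref_cols <- aln$aa[aln$reference, ] != "-"
    if (!any(ref_cols)) return(NA_real_)
    return(100 * sum(aln$column_class == "conserved" & ref_cols) /
             sum(ref_cols))
  }
  members <- rownames(aln$aa)
  pairs <- utils::combn(members, 2, simplify = FALSE)
  ident <- vapply(pairs, function(pr) {
    a <- aln$aa[pr[1], ]; b <- aln$aa[pr[2], ]
    ok <- a != "-" & b != "-"
    if (!any(ok)) return(NA_real_)
    mean(a[ok] == b[ok])
  }, numeric(1))
  100 * mean(ident, na.rm = TRUE)
}
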