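#' Correspondence analysis of a genes x codons table
#'
#' Standard (simple) correspondence analysis of a non-negative matrix, as
#' applied to raw codon counts or per-gene RSCU values: with grand total n,
#' correspondence matrix P = N/n, row and column masses r and c, the matrix
#' of standardized residuals S = Dr^-1/2 (P - r c') Dc^-1/2 is decomposed
#' by SVD; row/column principal coordinates and column standard coordinates
#' follow from the transition formulas. Dimensions are ordered by
#' decreasing inertia (squared singular value) and the sign of each
#' dimension is fixed so that the column with the largest absolute standard
#' coordinate loads positively, making results deterministic.
#'
#' @param mat Non-negative numeric matrix (genes x codons). All-zero rows
#'   or columns are dropped with a warning.
#' @param input_kind Label recorded in the result: `"rcc"` (raw codon
#'   counts) or `"rscu"`.
#'
#' @return Object of class `codon_ca`: list with `row_coords`,
#'   `col_coords` (principal), `col_standard`, `sv` (singular values),
#'   `inertia`, `percent_variance`, `row_mass`, `col_mass`, `total_inertia`,
#'   `dropped` (names of removed rows/columns), and `input_kind`.
#'
#' @examples
#' m <- matrix(rpois(80, 10), 8, 10,
#'             dimnames = list(paste0("g", 1:8), paste0("c", 1:10)))
#' fit <- ca_fit(m)
#' fit$percent_variance
#' @export
ca_fit <- function(mat, input_kind = c("rcc", "rscu")) {
  input_kind <- match.arg(input_kind)
  if (any(mat < 0)) stop("correspondence analysis input must be non-negative")
  dropped <- list(rows = character(0), cols = character(0))
  rz <- rowSums(mat) == 0
  cz <- colSums(mat) == 0
  if (any(rz) || any(cz)) {
    warning("dropping ", sum(rz), " all-zero row(s) and ", sum(cz),
            " all-zero column(s)")
    dropped$rows <- rownames(mat)[rz]
    dropped$cols <- colnames(mat)[cz]
    mat <- mat[!rz, !cz, drop = FALSE]
  }
  if (nrow(mat) < 2 || ncol(mat) < 2) {
    stop("need at least 2 non-zero rows and columns")
  }
  n <- sum(mat)
  p <- mat / n
  r <- rowSums(p)
  cc <- colSums(p)
  s <- sweep(sweep(p - outer(r, cc), 1, sqrt(r), "/"), 2, sqrt(cc), "/")
  total_inertia <- sum(s^2)
  if (total_inertia < 1e-14) stop("no inertia: all row profiles identical")
  sv <- svd(s)
  keep <- sv$d > max(sv$d) * 1e-9
  if (!any(keep)) stop("no inertia: rank-0 residual matrix")
  d <- sv$d[keep]
  u <- sv$u[, keep, drop = FALSE]
  v <- sv$v[, keep, drop = FALSE]
  col_standard <- sweep(v, 1, sqrt(cc), "/")
  # deterministic sign convention per dimension
  for (kdim in seq_along(d)) {
    j <- which.max(abs(col_standard[, kdim]))
    if (col_standard[j, kdim] < 0) {
      u[, kdim] <- -u[, kdim]
      v[, kdim] <- -v[, kdim]
      col_standard[, kdim] <- -col_standard[, kdim]
    }
  }
  row_coords <- sweep(u, 1, sqrt(r), "/") %*% diag(d, length(d))
  col_coords <- col_standard %*% diag(d, length(d))
  dn <- paste0("Dim", seq_along(d))
  dimnames(row_coords) <- list(rownames(mat), dn)
  dimnames(col_coords) <- list(colnames(mat), dn)
  dimnames(col_standard) <- list(colnames(mat), dn)
  inertia <- d^2
  structure(
    list(row_coords = row_coords, col_coords = col_coords,
         col_standard = col_standard, sv = d, inertia = inertia,
         percent_variance = 100 * inertia / sum(inertia),
         row_mass = r, col_mass = cc, total_inertia = total_inertia,
         dropped = dropped, input_kind = input_kind),
    class = "codon_ca"
  )
}

#' @export
print.codon_ca <- function(x, ...) {
  cat("Correspondence analysis (", toupper(x$input_kind), " input): ",
      nrow(x$row_coords), " rows x ", nrow(x$col_coords), " columns\n",
      sep = "")
  cat("  total inertia ", format(round(x$total_inertia, 6)),
      "; Dim1 ", sprintf("%.1f%%", x$percent_variance[1]),
      if (length(x$percent_variance) > 1)
        sprintf(", Dim2 %.1f%%", x$percent_variance[2]), "\n", sep = "")
  invisible(x)
}

#' Project supplementary rows onto a fitted CA space
#'
#' Supplementary rows (e.g. modal sequences, pooled gene sets) are placed
#' in an existing CA space without influencing it: their row profiles are
#' multiplied by the column standard coordinates. An exact copy of an
#' active row lands on that row's principal coordinates.
#'
#' @param fit A [ca_fit()] result.
#' @param rows Non-negative matrix (or single named vector) whose columns
#'   match the fit's retained columns.
#' @return Matrix of principal coordinates, one row per supplementary row.
#' @export
ca_project <- function(fit, rows) {
  if (is.null(dim(rows))) rows <- matrix(rows, 1,
                                         dimnames = list("sup", names(rows)))
  cols <- rownames(fit$col_standard)
  missing <- setdiff(cols, colnames(rows))
  if (length(missing)) {
    stop("supplementary rows lack fitted columns: ",
         paste(utils::head(missing, 8), collapse = ", "))
  }
  rows <- rows[, cols, drop = FALSE]
  if (any(rows < 0)) stop("supplementary rows must be non-negative")
  prof <- sweep(rows, 1, rowSums(rows), "/")
  coords <- prof %*% fit$col_standard
  rownames(coords) <- rownames(rows)
  coords
}

#' Gene-set centroids in CA space
#'
#' Arithmetic mean of the row principal coordinates of each gene set, the
#' quantity used to track how a set's codon usage shifts along the main
#' axes of variation.
#'
#' @param fit A [ca_fit()] result.
#' @param partition Either a named list (set -> gene ids) or a data frame
#'   with columns `gene` and `set`.
#' @param dims Dimensions to average (default first two).
#' @return Matrix, sets x dims. Sets with no gene among the active rows
#'   are skipped with a warning.
#' @export
set_centroids <- function(fit, partition, dims = 1:2) {
  if (is.data.frame(partition)) {
    partition <- split(as.character(partition$gene),
                       as.character(partition$set))
  }
  dims <- dims[dims <= ncol(fit$row_coords)]
  out <- matrix(NA_real_, length(partition), length(dims),
                dimnames = list(names(partition),
                                colnames(fit$row_coords)[dims]))
  for (s in names(partition)) {
    genes <- intersect(partition[[s]], rownames(fit$row_coords))
    if (!length(genes)) {
      warning("set '", s, "' has no gene among the active rows; skipped")
      next
    }
    out[s, ] <- colMeans(fit$row_coords[genes, dims, drop = FALSE])
  }
  out[!is.na(out[, 1]), , drop = FALSE]
}

#' Plot a codon CA
#'
#' Scatter of genes in the first two dimensions with optional gene-set
#' centroids overlaid; cosmetic companion to [ca_fit()].
#'
#' @param x A `codon_ca` object.
#' @param partition Optional partition for centroid overlay
#'   (see [set_centroids()]).
#' @param ... Passed to [plot()].
#' @export
plot.codon_ca <- function(x, partition = NULL, ...) {
  xl <- sprintf("Dim 1 (%.1f%%)", x$percent_variance[1])
  yl <- sprintf("Dim 2 (%.1f%%)", x$percent_variance[2])
  graphics::plot(x$row_coords[, 1], x$row_coords[, 2], pch = 16,
                 col = "grey70", xlab = xl, ylab = yl, ...)
  if (!is.null(partition)) {
    cen <- set_centroids(x, partition)
    graphics::points(cen[, 1], cen[, 2], pch = 17, col = "red3", cex = 1.4)
    graphics::text(cen[, 1], cen[, 2], rownames(cen), pos = 3, col = "red3")
  }
  invisible(x)
}
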