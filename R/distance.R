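#' Distance between two codon usage profiles
#'
#' Amino-acid-frequency-weighted per-family L1 distance:
#' D = sum over amino acids of m_aa * 1/2 * sum over the family of
#' |cuf1 - cuf2|, with m_aa the mean of the two profiles' amino-acid
#' frequencies. Rare amino acids therefore contribute little even when
#' their within-family usage differs strongly. Only families defined in
#' both profiles enter; D is symmetric, zero on identical profiles, and
#' satisfies the triangle inequality.
#'
#' @param p1,p2 [usage_profile()] objects.
#' @param code A [genetic_code()].
#' @return A non-negative scalar.
#' @export
usage_distance <- function(p1, p2, code = genetic_code()) {
  aa <- codon_aa(code, code$codons)
  shared <- !is.na(p1$cuf) & !is.na(p2$cuf)
  if (!any(shared)) stop("profiles share no defined codon families")
  d <- 0
  for (a in unique(aa[shared])) {
    idx <- shared & aa == a
    m_aa <- (p1$aa_freq[[a]] + p2$aa_freq[[a]]) / 2
    d <- d + m_aa * 0.5 * sum(abs(p1$cuf[idx] - p2$cuf[idx]))
  }
  d
}

#' Pairwise usage-distance matrix
#'
#' Applies [usage_distance()] to every pair in a named list of profiles.
#'
#' @param profiles Named list of `usage_profile`s.
#' @param code A [genetic_code()].
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
usage_distance_matrix <- function(profiles, code = genetic_code()) {
  n <- length(profiles)
  labs <- names(profiles)
  dm <- matrix(0, n, n, dimnames = list(labs, labs))
  if (n < 2) return(dm)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dm[i, j] <- dm[j, i] <- usage_distance(profiles[[i]], profiles[[j]],
                                           code)
  }
  dm
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining with two determinism guarantees: when
#' several pairs attain the minimal Q criterion the pair with the lowest
#' (row, column) index is joined, and a negative branch length arising at
#' a join is clamped to zero with the deficit moved to its sibling branch
#' so the pair's total distance is preserved.
#'
#' @param dm Symmetric non-negative distance matrix with at least 3
#'   labelled rows.
#' @return An [ape::phylo] unrooted tree whose tips are the matrix labels.
#' @export
nj_tree <- function(dm) {
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-8))) {
    stop("distance matrix must be symmetric")
  }
  if (any(dm < 0)) stop("distances must be non-negative")
  n <- nrow(dm)
  if (n < 3) stop("need at least 3 taxa")
  labs <- rownames(dm)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))

  # node bookkeeping: tips 1..n, internal nodes appended as created
  ids <- seq_len(n)            # current active node ids
  next_id <- n + 1L
  edges <- matrix(0L, 0, 2)
  lens <- numeric(0)
  d <- dm

  add_edge <- function(parent, child, len) {
    edges <<- rbind(edges, c(parent, child))
    lens <<- c(lens, len)
  }

  while (length(ids) > 3) {
    r <- length(ids)
    R <- rowSums(d)
    q <- (r - 2) * d - outer(R, R, "+")
    diag(q) <- Inf
    # lowest-index tie break: scan i < j in order
    best <- c(NA, NA); bestq <- Inf
    for (i in 1:(r - 1)) for (j in (i + 1):r) {
      if (q[i, j] < bestq - 1e-12) {
        bestq <- q[i, j]; best <- c(i, j)
      }
    }
    i <- best[1]; j <- best[2]
    vi <- 0.5 * d[i, j] + (R[i] - R[j]) / (2 * (r - 2))
    vj <- d[i, j] - vi
    if (vi < 0) { vj <- d[i, j]; vi <- 0 }
    if (vj < 0) { vi <- d[i, j]; vj <- 0 }
    new <- next_id; next_id <- next_id + 1L
    add_edge(new, ids[i], vi)
    add_edge(new, ids[j], vj)
    dnew <- 0.5 * (d[i, -c(i, j)] + d[j, -c(i, j)] - d[i, j])
    dnew <- pmax(dnew, 0)
    keep <- setdiff(seq_len(r), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dnew),
               c(dnew, 0))
    ids <- c(ids[keep], new)
  }
  # resolve the final 3-star with the closed-form three-point formulas
  va <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  vb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  vc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  hub <- next_id; next_id <- next_id + 1L
  add_edge(hub, ids[1], max(va, 0))
  add_edge(hub, ids[2], max(vb, 0))
  add_edge(hub, ids[3], max(vc, 0))

  # renumber to ape convention: tips 1..n, root-ish internal nodes n+1..
  internal <- sort(unique(edges[edges > n]))
  remap <- integer(max(edges))
  remap[seq_len(n)] <- seq_len(n)
  # hub (last created) becomes n+1 so the edge matrix is rooted at it
  ord <- c(hub, rev(setdiff(internal, hub)))
  remap[ord] <- n + seq_along(ord)
  edges2 <- matrix(remap[edges], ncol = 2)
  tree <- structure(
    list(edge = edges2, edge.length = lens, tip.label = labs,
         Nnode = length(internal)),
    class = "phylo", order = NULL)
  stats::reorder(tree, "cladewise")
}

#' Natural versus simulated divergence ratio
#'
#' Ratio of the same entry in two usage-distance matrices, typically the
#' HEP_cr to LEP_vr distance in natural gene sets over the matching
#' distance in sequences evolved with no pressure for codon selection.
#' Values above 1 indicate that the natural codon usages are more
#' divergent, i.e. positively adapted.
#'
#' @param natural,simulated Distance matrices sharing the two labels.
#' @param from_label,to_label Names of the compared gene sets.
#' @return The scalar ratio natural / simulated.
#' @export
selection_ratio <- function(natural, simulated, from_label, to_label) {
  for (dmn in list(natural, simulated)) {
    if (!all(c(from_label, to_label) %in% rownames(dmn))) {
      stop("labels not present in both matrices")
    }
  }
  den <- simulated[from_label, to_label]
  if (den == 0) stop("simulated distance is zero; ratio undefined")
  natural[from_label, to_label] / den
}
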