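#' Run the full codon-usage selection analysis
#'
#' Orchestrates the whole pipeline on one genome: codon counting, per-set
#' pooled profiles with GC3 and Nc, modal usages, correspondence analysis
#' with set centroids and modal-sequence projection, Sij training and
#' adaptiveness, per-set m-tAI, C/U bias tests between the most and least
#' ancestral cores, and the diversity-group call. When abundance data and
#' ortholog alignments are supplied the HEP/LEP conserved/variable domain
#' stages and the usage-distance NJ tree run as well; otherwise those
#' stages are skipped with a notice. Writing of artifacts (TSV/FASTA/
#' Newick plus a manifest with content hashes) is optional.
#'
#' @param sequences Named character vector of CDS (or a FASTA path).
#' @param partition Data frame gene/set (or a TSV path); set names must
#'   include `singletons`, `PHE`, and `C1..Cn` in ancestry order.
#' @param trna_pool Named anticodon copy-number vector (or TSV path). When
#'   NULL, Sij training and m-tAI stages are skipped.
#' @param abundance Optional named abundance vector (or TSV path) enabling
#'   HEP/LEP selection.
#' @param alignments Optional named list of ortholog families, each a list
#'   with `aa_alignment` and `cds` (see [backthread()]), enabling the
#'   cr/vr stages.
#' @param p_cutoff Modal-usage consistency cutoff.
#' @param sij_restarts,seed Sij training control.
#' @param out_dir Optional output directory for artifacts + manifest.
#' @param code A [genetic_code()].
#' @return List of class `codonsel_run` with one element per completed
#'   stage and a `skipped` character vector.
#' @export
run_full_analysis <- function(sequences, partition, trna_pool = NULL,
                              abundance = NULL, alignments = NULL,
                              p_cutoff = 0.1, sij_restarts = 10L,
                              seed = 1L, out_dir = NULL,
                              code = genetic_code()) {
  if (is.character(sequences) && length(sequences) == 1 &&
      file.exists(sequences)) {
    sequences <- read_cds_fasta(sequences)
  }
  if (is.character(partition)) partition <- read_partition_table(partition)
  if (is.character(trna_pool)) trna_pool <- read_trna_table(trna_pool)
  if (is.character(abundance)) abundance <- read_abundance_table(abundance)

  skipped <- character(0)
  sets <- order_sets(unique(partition$set))
  by_set <- split(partition$gene, partition$set)[sets]

  counts <- count_codons(sequences, code)
  set_counts <- lapply(by_set, function(g) pool_counts(counts, g))
  profiles <- lapply(set_counts, usage_profile, code = code)
  nc <- vapply(set_counts, function(x) {
    suppressWarnings(effective_number_of_codons(x, code))
  }, numeric(1))
  gc3 <- vapply(set_counts, gc3_content, numeric(1), code = code)

  modals <- lapply(by_set, function(g) {
    modal_usage(counts[g, , drop = FALSE], p_cutoff = p_cutoff, code = code)
  })
  modal_seqs <- vapply(modals, function(m) modal_sequence(m$profile,
                                                          code = code),
                       character(1))

  fit <- ca_fit(counts, "rcc")
  centroids <- set_centroids(fit, by_set)
  modal_proj <- ca_project(fit, count_codons(modal_seqs, code))

  tai_res <- NULL
  if (!is.null(trna_pool)) {
    sij <- train_sij(counts, trna_pool, restarts = sij_restarts,
                     seed = seed, code = code)
    adapt <- absolute_adaptiveness(trna_pool, sij$s, code)
    mtai <- vapply(modals, function(m) modal_tai(m$profile, adapt, code),
                   numeric(1))
    tai_res <- list(sij = sij, adaptiveness = adapt, mtai = mtai)
  } else {
    skipped <- c(skipped, "sij_training", "mtai")
  }

  cores <- grep("^C[0-9]+$", sets, value = TRUE)
  bias_res <- NULL
  if (length(cores) >= 2) {
    d <- delta_cuf(profiles[[cores[length(cores)]]], profiles[[cores[1]]],
                   code)
    bias_res <- list(delta = d, c_bias = c_bias_test(d),
                     u_bias = u_bias_test(d))
  } else {
    skipped <- c(skipped, "bias_tests")
  }

  group <- NULL
  if (all(c("singletons", "PHE") %in% sets) && length(cores) >= 1) {
    gc_total <- gc_content(pool_counts(counts), code)
    group <- classify_group(gc_total,
                            gc3_singletons = gc3[["singletons"]],
                            gc3_core = gc3[[cores[length(cores)]]],
                            gc3_phe = gc3[["PHE"]])
  } else {
    skipped <- c(skipped, "group_call")
  }

  crvr <- NULL
  dist_res <- NULL
  if (!is.null(abundance) && !is.null(alignments) && length(cores)) {
    core_genes <- unlist(by_set[cores], use.names = FALSE)
    hl <- select_hep_lep(abundance, core_genes)
    dom <- list()
    for (grp in c("hep", "lep")) {
      fams <- alignments[names(alignments) %in% hl[[grp]]]
      for (cls in c("cr", "vr")) {
        pieces <- vapply(fams, function(f) {
          aln <- classify_columns(backthread(f$aa_alignment, f$cds,
                                             code = code))
          suppressWarnings(extract_domains(aln, cls))
        }, character(1))
        dom[[paste0(toupper(grp), "_", cls)]] <-
          paste(pieces[nchar(pieces) > 0], collapse = "")
      }
    }
    dom <- dom[vapply(dom, nchar, integer(1)) > 0]
    crvr <- dom
    if (length(dom) >= 3) {
      dom_profiles <- lapply(dom, function(s) {
        usage_profile(count_codons(stats::setNames(s, "d"), code), code)
      })
      dm <- usage_distance_matrix(dom_profiles, code)
      dist_res <- list(distances = dm, tree = nj_tree(dm))
    } else {
      skipped <- c(skipped, "distance_tree")
    }
  } else {
    skipped <- c(skipped, "crvr", "distance_tree")
  }

  res <- structure(
    list(counts = counts, profiles = profiles, nc = nc, gc3 = gc3,
         modal = modals, modal_sequences = modal_seqs, ca = fit,
         centroids = centroids, modal_projection = modal_proj,
         tai = tai_res, bias = bias_res, group = group, crvr = crvr,
         distance = dist_res, sets = sets, seed = seed,
         skipped = unique(skipped)),
    class = "codonsel_run"
  )
  if (!is.null(out_dir)) write_run_artifacts(res, out_dir)
  res
}

# natural ancestry order: singletons, C1..Cn (numeric), PHE, then others
order_sets <- function(sets) {
  cores <- sort(as.integer(sub("^C", "", grep("^C[0-9]+$", sets,
                                              value = TRUE))))
  ordered <- c(intersect("singletons", sets), paste0("C", cores),
               intersect("PHE", sets))
  c(ordered, setdiff(sets, ordered))
}

#' @export
print.codonsel_run <- function(x, ...) {
  cat("codonsel run over", nrow(x$counts), "genes in",
      length(x$sets), "sets:", paste(x$sets, collapse = " < "), "\n")
  if (!is.null(x$tai)) {
    cat("  m-tAI:", paste(sprintf("%s %.3f", names(x$tai$mtai),
                                  x$tai$mtai), collapse = ", "), "\n")
  }
  if (!is.null(x$bias)) {
    cat("  C bias p =", format.pval(x$bias$c_bias$p.value, digits = 3),
        "; U bias p =", format.pval(x$bias$u_bias$p.value, digits = 3),
        "\n")
  }
  if (!is.null(x$group)) cat("  diversity group:", x$group$group, "\n")
  if (length(x$skipped)) {
    cat("  skipped stages:", paste(x$skipped, collapse = ", "), "\n")
  }
  invisible(x)
}

# write TSV/FASTA/Newick artifacts plus a manifest with md5 hashes
write_run_artifacts <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  p <- function(name) file.path(out_dir, name)
  write_matrix_tsv(res$counts, p("codon_counts.tsv"))
  paths <- c(paths, p("codon_counts.tsv"))
  write_matrix_tsv(res$centroids, p("ca_centroids.tsv"), "set")
  paths <- c(paths, p("ca_centroids.tsv"))
  write_matrix_tsv(res$ca$row_coords, p("ca_row_coords.tsv"))
  paths <- c(paths, p("ca_row_coords.tsv"))
  for (s in names(res$modal)) {
    f <- p(paste0("modal_", s, ".tsv"))
    write_profile_tsv(res$modal[[s]]$profile, f)
    paths <- c(paths, f)
  }
  seqs <- res$modal_sequences
  names(seqs) <- sprintf("modal|%s|n=%d", names(seqs),
                         nchar(seqs) %/% 3L)
  write_fasta(seqs, p("modal_sequences.fasta"))
  paths <- c(paths, p("modal_sequences.fasta"))
  if (!is.null(res$tai)) {
    utils::write.table(res$tai$adaptiveness, p("adaptiveness.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p("adaptiveness.tsv"))
    jsonlite::write_json(
      list(s = as.list(unclass(res$tai$sij$s)), rho = res$tai$sij$rho,
           seed = res$tai$sij$seed),
      p("sij_weights.json"), auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p("sij_weights.json"))
  }
  if (!is.null(res$distance)) {
    write_matrix_tsv(res$distance$distances, p("usage_distances.tsv"),
                     "set")
    ape::write.tree(res$distance$tree, p("usage_tree.nwk"))
    paths <- c(paths, p("usage_distances.tsv"), p("usage_tree.nwk"))
  }
  manifest <- data.frame(
    file = basename(paths),
    md5 = as.character(tools::md5sum(paths)),
    seed = res$seed, stringsAsFactors = FALSE)
  utils::write.table(manifest, p("MANIFEST.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
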