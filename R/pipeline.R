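# End-to-end orchestration: polarize -> search -> root -> annotate -> report.

#' Run the full polarity/parsimony pipeline
#'
#' Executes the whole analysis chain on an expression matrix and study
#' design and writes all artifacts to `out_dir`: the polarity matrix (state
#' and binary TSVs), the per-gene class report, the DEA gene list, the
#' most-parsimonious cladogram in Newick (plus the strict consensus when
#' several co-optimal trees are found), the per-node synapomorphy reports,
#' the heat-map coding of the most deregulated genes, and a run log
#' recording the configuration and every decision taken (excluded genes,
#' search method, number of optima). Outputs are deterministic given the
#' inputs and seed.
#'
#' @param matrix an [expression_matrix] or a path to one.
#' @param design a `study_design` or a path to a design file.
#' @param out_dir output directory, created if absent.
#' @param format input format when `matrix` is a path.
#' @param log2 apply the optional `log2(x + 1)` preprocessing (default off).
#' @param tolerance fractional widening of the outgroup interval.
#' @param leave_one_out code outgroup samples against the leave-one-out
#'   interval (default TRUE).
#' @param model parsimony model, `"wagner"` (default) or `"camin_sokal"`.
#' @param seed,n_starts heuristic-search parameters.
#' @param max_exhaustive_taxa problems up to this many taxa are solved
#'   exactly; larger ones heuristically.
#' @param taxa leaves of the tree; default all analyzed samples.
#' @param heatmap_n number of genes in the heat-map export (ranked by
#'   ingroup deregulation breadth, DEA genes first).
#' @return invisibly, a list with all in-memory artifacts
#'   (`polarity`, `classes`, `dea`, `trees`, `cladogram`, `annotated`,
#'   `heatmap`, `files`).
#' @export
run_pipeline <- function(matrix, design, out_dir,
                         format = c("tsv", "geo_series_matrix"),
                         log2 = FALSE, tolerance = 0, leave_one_out = TRUE,
                         model = c("wagner", "camin_sokal"), seed = 42,
                         n_starts = 20, max_exhaustive_taxa = 9, taxa = NULL,
                         heatmap_n = 16) {
  format <- match.arg(format)
  model <- match.arg(model)
  if (is.character(matrix)) matrix <- read_expression_table(matrix, format)
  if (is.character(design)) design <- read_design(design, matrix)
  stopifnot(inherits(matrix, "expression_matrix"),
            inherits(design, "study_design"))
  if (log2) matrix <- log2_transform(matrix)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("expclad %s on R %s.%s", packageVersion("expclad"),
                         R.version$major, R.version$minor),
                 sprintf("samples: %d outgroup, %d ingroup, %d unassigned",
                         length(design$outgroup), length(design$ingroup),
                         length(design$unassigned)),
                 sprintf("config: log2=%s tolerance=%g leave_one_out=%s model=%s seed=%d n_starts=%d",
                         log2, tolerance, leave_one_out, model, seed, n_starts))

  profile <- outgroup_profile(matrix, design, tolerance)
  polarity <- polarize(matrix, profile, design, leave_one_out)
  log_lines <- c(log_lines,
                 sprintf("excluded genes (outgroup n_obs < 2): %d%s",
                         length(polarity$excluded_genes),
                         if (length(polarity$excluded_genes))
                           paste0(" [", paste(polarity$excluded_genes,
                                              collapse = ", "), "]")
                         else ""))

  classes <- classify_genes(polarity)
  dea <- detect_dea(polarity)

  taxa <- taxa %||% colnames(polarity$states)
  trees <- if (length(taxa) <= max_exhaustive_taxa)
    exhaustive_search(polarity, model, taxa = taxa)
  else
    heuristic_search(polarity, model, seed = seed, n_starts = n_starts,
                     taxa = taxa)
  log_lines <- c(log_lines,
                 sprintf("search: %s, %d taxa, length %d, %g optimal tree(s)",
                         trees$method, length(taxa), trees$length,
                         trees$n_opt))
  cladogram <- root_cladogram(trees$trees[[1]], polarity)
  annotated <- annotate_cladogram(cladogram, polarity)

  # rank genes by ingroup deregulation breadth for the heat-map, DEA first
  derived_n <- classes$n_over + classes$n_under + classes$n_absent
  ord <- order(classes$class != "dea", -derived_n, classes$gene_id)
  hm_genes <- classes$gene_id[ord][seq_len(min(heatmap_n, nrow(classes)))]
  leaf_order <- annotated$tree$tip.label
  hm_samples <- intersect(leaf_order, polarity$ingroup)
  if (!length(hm_samples)) hm_samples <- leaf_order
  hm <- heatmap_codes(polarity, hm_genes, hm_samples)

  files <- list(
    polarity = file.path(out_dir, "polarity.tsv"),
    binary = file.path(out_dir, "polarity_binary.tsv"),
    classes = file.path(out_dir, "gene_classes.tsv"),
    dea = file.path(out_dir, "dea_genes.txt"),
    cladogram = file.path(out_dir, "cladogram.nwk"),
    consensus = file.path(out_dir, "cladogram_consensus.nwk"),
    nodes = file.path(out_dir, "synapomorphy_nodes.tsv"),
    genes = file.path(out_dir, "synapomorphy_genes.tsv"),
    heatmap = file.path(out_dir, "heatmap_codes.tsv"),
    log = file.path(out_dir, "run_log.txt"))

  write_polarity(polarity, files$polarity)
  write_polarity(polarity, files$binary, binary = TRUE)
  write.table(classes, files$classes, sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(dea, files$dea)
  ape::write.tree(annotated$tree, files$cladogram)
  if (length(trees$trees) > 1) {
    ape::write.tree(strict_consensus(trees), files$consensus)
  } else {
    files$consensus <- NULL
  }
  write_synapomorphy_report(annotated, files$nodes, files$genes)
  writeLines(c(paste(c("gene_id", colnames(hm)), collapse = "\t"),
               paste(rownames(hm), apply(hm, 1, paste, collapse = "\t"),
                     sep = "\t")), files$heatmap)
  writeLines(log_lines, files$log)

  invisible(list(polarity = polarity, classes = classes, dea = dea,
                 trees = trees, cladogram = cladogram, annotated = annotated,
                 heatmap = hm, files = files, log = log_lines))
}
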