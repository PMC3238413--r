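# Synthetic expression data with planted phylogenetic structure, plus the
# ground-truth bookkeeping needed to score recovery.

#' Simulation configuration
#'
#' Parameters of the synthetic-data generator. Defaults describe the clean
#' benchmark condition used throughout the package: 8 outgroup and 10
#' ingroup samples, 2,000 genes, 5 derived-expression events per internal
#' branch of the planted tree, displacement 2 baseline-SD beyond the
#' realized outgroup range, and no noise, DEA planting or missingness
#' (corruption processes are opted in per run).
#'
#' Per-gene baselines are lognormal: `meanlog` uniform over
#' `baseline_mu_range`, `sdlog = baseline_sd`. `effect_size` and `noise_sd`
#' are both expressed in units of the gene's baseline standard deviation on
#' the data scale.
#'
#' @param n_genes number of genes.
#' @param n_outgroup number of outgroup samples (>= 2).
#' @param n_ingroup number of ingroup samples (used when no tree is given).
#' @param planted_tree rooted binary `phylo` over the ingroup sample names,
#'   or `NULL` to draw a random rooted topology under the seed.
#' @param events_per_branch events planted on each internal branch: a
#'   scalar, a named vector `N<id> -> count`, or a named list
#'   `N<id> -> c(over = , under = )` fixing the direction split.
#' @param effect_size displacement beyond the realized outgroup min/max, in
#'   baseline-SD units.
#' @param baseline_mu_range range of the lognormal `meanlog` across genes.
#' @param baseline_sd lognormal `sdlog`, shared by all genes.
#' @param noise_sd Gaussian measurement noise, in baseline-SD units, added
#'   to every cell last.
#' @param dea_fraction fraction of planted events converted to DEA events
#'   (the clade's leaves split at random into an over half and an under
#'   half).
#' @param missing_fraction fraction of ingroup cells masked as missing.
#' @param seed integer RNG seed.
#' @export
simulation_config <- function(n_genes = 2000, n_outgroup = 8, n_ingroup = 10,
                              planted_tree = NULL, events_per_branch = 5,
                              effect_size = 2, baseline_mu_range = c(3, 8),
                              baseline_sd = 0.3, noise_sd = 0,
                              dea_fraction = 0, missing_fraction = 0,
                              seed = 1) {
  stopifnot(n_genes >= 1, n_outgroup >= 2, n_ingroup >= 3,
            effect_size > 0, baseline_sd > 0, noise_sd >= 0,
            dea_fraction >= 0, dea_fraction <= 1,
            missing_fraction >= 0, missing_fraction <= 1,
            length(baseline_mu_range) == 2,
            baseline_mu_range[1] <= baseline_mu_range[2])
  if (!is.null(planted_tree)) {
    stopifnot(inherits(planted_tree, "phylo"))
    if (!ape::is.rooted(planted_tree)) stop("planted_tree must be rooted")
  }
  structure(list(n_genes = n_genes, n_outgroup = n_outgroup,
                 n_ingroup = n_ingroup, planted_tree = planted_tree,
                 events_per_branch = events_per_branch,
                 effect_size = effect_size,
                 baseline_mu_range = baseline_mu_range,
                 baseline_sd = baseline_sd, noise_sd = noise_sd,
                 dea_fraction = dea_fraction,
                 missing_fraction = missing_fraction, seed = seed),
            class = "simulation_config")
}

# internal-node labels "N<ape id>" and member lists of a rooted tree
internal_nodes <- function(tree) {
  ntip <- length(tree$tip.label)
  members <- node_members(tree)
  ids <- seq(ntip + 1L, ntip + tree$Nnode)
  setNames(members[ids], paste0("N", ids))
}

build_event_table <- function(cfg, tree) {
  clades <- internal_nodes(tree)
  epb <- cfg$events_per_branch
  rows <- list()
  for (nid in names(clades)) {
    spec <- if (is.list(epb) || length(epb) > 1) {
      if (nid %in% names(epb)) epb[[nid]] else 0
    } else epb
    if (is.null(spec)) spec <- 0
    if (length(spec) == 2 && !is.null(names(spec))) {
      dirs <- c(rep("over", spec[["over"]]), rep("under", spec[["under"]]))
    } else {
      n <- as.integer(spec)
      if (n == 0) next
      dirs <- sample(c("over", "under"), n, replace = TRUE)
    }
    if (!length(dirs)) next
    rows[[nid]] <- data.frame(node = nid, direction = dirs)
  }
  ev <- do.call(rbind, rows)
  if (is.null(ev)) ev <- data.frame(node = character(), direction = character())
  rownames(ev) <- NULL
  ev
}

#' Simulate an expression dataset with planted phylogenetic structure
#'
#' Outgroup values are drawn from each gene's lognormal baseline; ingroup
#' baselines are drawn from the same lognormal truncated to the realized
#' outgroup range, so that in the absence of events and noise every ingroup
#' value polarizes ancestral. For each planted event on branch/clade `C` with direction over
#' (under), every ingroup sample in `C` is displaced above the realized
#' outgroup max (below the min) by `effect_size` baseline-SDs; DEA events
#' displace two random halves of the clade in opposite directions. Gaussian
#' noise is added to every cell last, and a fraction of ingroup cells is
#' masked missing. Deterministic given the config seed.
#'
#' @param config a [simulation_config()].
#' @return list with `matrix` (an [expression_matrix]), `design` (a
#'   `study_design`), and `truth` (class `synthetic_truth`: the planted tree
#'   with labelled internal nodes, the per-branch event table with clade
#'   membership, per-gene class labels, and the config echo).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  local_seed(config$seed, {
    tree <- config$planted_tree %||%
      ape::rtopology(config$n_ingroup, rooted = TRUE, br = NULL,
                     tip.label = sprintf("I%02d", seq_len(config$n_ingroup)))
    ing <- tree$tip.label
    outg <- sprintf("O%d", seq_len(config$n_outgroup))
    ng <- config$n_genes
    genes <- sprintf("g%04d", seq_len(ng))
    ntip <- length(ing)
    tree$node.label <- paste0("N", seq(ntip + 1L, ntip + tree$Nnode))

    events <- build_event_table(config, tree)
    if (nrow(events) > ng)
      stop("planted events (", nrow(events), ") exceed n_genes (", ng, ")")
    clades <- internal_nodes(tree)

    meanlog <- runif(ng, config$baseline_mu_range[1], config$baseline_mu_range[2])
    s <- config$baseline_sd
    sd_g <- sqrt(exp(s^2) - 1) * exp(meanlog + s^2 / 2)  # data-scale SD

    out_vals <- matrix(stats::rlnorm(ng * length(outg), meanlog, s),
                       nrow = ng, dimnames = list(genes, outg))
    out_min <- row_min(out_vals)
    out_max <- row_max(out_vals)
    # ingroup baselines: the gene's lognormal truncated to the realized
    # outgroup range, so a non-event noise-free cell polarizes ancestral
    plo <- stats::plnorm(out_min, meanlog, s)
    phi <- stats::plnorm(out_max, meanlog, s)
    u <- matrix(runif(ng * length(ing), rep(plo, length(ing)),
                      rep(phi, length(ing))), nrow = ng)
    in_vals <- matrix(stats::qlnorm(u, rep(meanlog, length(ing)), s),
                      nrow = ng, dimnames = list(genes, ing))

    if (nrow(events)) {
      events$gene_id <- sample(genes, nrow(events))
      if (config$dea_fraction > 0) {
        n_dea <- round(config$dea_fraction * nrow(events))
        if (n_dea > 0)
          events$direction[sample.int(nrow(events), n_dea)] <- "dea"
      }
      for (i in seq_len(nrow(events))) {
        g <- events$gene_id[i]
        leaves <- clades[[events$node[i]]]
        d <- config$effect_size * sd_g[match(g, genes)]
        if (events$direction[i] == "dea") {
          half <- sample(leaves, ceiling(length(leaves) / 2))
          in_vals[g, half] <- out_max[match(g, genes)] + d
          in_vals[g, setdiff(leaves, half)] <- out_min[match(g, genes)] - d
        } else if (events$direction[i] == "over") {
          in_vals[g, leaves] <- out_max[match(g, genes)] + d
        } else {
          in_vals[g, leaves] <- out_min[match(g, genes)] - d
        }
      }
    } else {
      events$gene_id <- character()
    }

    vals <- cbind(out_vals, in_vals)
    if (config$noise_sd > 0)
      vals <- vals + matrix(rnorm(length(vals),
                                  sd = rep(config$noise_sd * sd_g,
                                           ncol(vals))),
                            nrow = ng)
    if (config$missing_fraction > 0) {
      cells <- length(ing) * ng
      n_miss <- round(config$missing_fraction * cells)
      if (n_miss > 0) {
        idx <- sample.int(cells, n_miss)
        ing_block <- vals[, ing, drop = FALSE]
        ing_block[idx] <- NA_real_
        vals[, ing] <- ing_block
      }
    }

    em <- expression_matrix(vals, genes, c(outg, ing))
    design <- build_design(outg, ing, em)

    gene_class <- setNames(rep("unchanged", ng), genes)
    if (nrow(events))
      gene_class[events$gene_id] <-
        c(over = "overexpressed", under = "underexpressed",
          dea = "dea")[events$direction]
    events$members <- vapply(clades[events$node], clade_key, "")

    truth <- structure(list(planted_tree = tree,
                            events = events[, c("node", "members", "gene_id",
                                                "direction")],
                            gene_class = gene_class, config = config),
                       class = "synthetic_truth")
    list(matrix = em, design = design, truth = truth)
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth: %d leaves, %d planted events on %d branches\n",
              length(x$planted_tree$tip.label), nrow(x$events),
              length(unique(x$events$node))))
  invisible(x)
}

#' Write the ground truth to disk
#' @param truth a `synthetic_truth`.
#' @param dir output directory (created if absent).
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ape::write.tree(truth$planted_tree, file.path(dir, "planted_tree.nwk"))
  write.table(truth$events, file.path(dir, "planted_events.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- truth$config
  cfg$planted_tree <- NULL
  writeLines(paste0(names(cfg), "=",
                    vapply(cfg, function(v) paste(v, collapse = ","), "")),
             file.path(dir, "sim_config.txt"))
  invisible(dir)
}

#' Score tree and synapomorphy recovery against the planted truth
#'
#' Compares an annotated inferred cladogram with the planted tree
#' ([rf_distance()]) and, for every planted branch, matches the inferred
#' node with identical clade membership and scores the inferred additional
#' synapomorphies against the planted event genes. Precision and recall are
#' pooled over all planted branches; a planted clade absent from the
#' inferred tree contributes zero recovered genes.
#'
#' @param inferred an `annotated_cladogram` over the ingroup samples.
#' @param truth a `synthetic_truth`.
#' @return object of class `recovery_report`: `rf`, pooled `precision` and
#'   `recall`, and the per-branch table `per_node`.
#' @export
evaluate_recovery <- function(inferred, truth) {
  stopifnot(inherits(inferred, "annotated_cladogram"),
            inherits(truth, "synthetic_truth"))
  tree_inf <- inferred$tree
  if (!setequal(tree_inf$tip.label, truth$planted_tree$tip.label))
    stop("leaf sets of inferred and planted trees differ")
  rf <- rf_distance(tree_inf, truth$planted_tree)

  inf_by_members <- setNames(inferred$gene_sets,
                             vapply(strsplit(inferred$nodes$members, ";"),
                                    clade_key, ""))
  planted_nodes <- unique(truth$events[, c("node", "members")])
  rows <- lapply(seq_len(nrow(planted_nodes)), function(i) {
    key <- planted_nodes$members[i]
    planted_genes <- truth$events$gene_id[truth$events$members == key]
    gs <- inf_by_members[[key]]
    add <- if (is.null(gs)) character() else gs$additional
    tp <- length(intersect(add, planted_genes))
    data.frame(node = planted_nodes$node[i], members = key,
               clade_recovered = !is.null(gs),
               n_planted = length(planted_genes), n_additional = length(add),
               n_true_positive = tp)
  })
  per_node <- do.call(rbind, rows)
  precision <- if (sum(per_node$n_additional) > 0)
    sum(per_node$n_true_positive) / sum(per_node$n_additional) else NA_real_
  recall <- if (sum(per_node$n_planted) > 0)
    sum(per_node$n_true_positive) / sum(per_node$n_planted) else NA_real_
  structure(list(rf = rf, precision = precision, recall = recall,
                 per_node = per_node),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("recovery_report: RF = %d, precision = %.3f, recall = %.3f\n",
              x$rf, x$precision, x$recall))
  invisible(x)
}
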