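# Clade synapomorphy extraction, additive cladogram annotation, per-branch
# change mapping and heat-map coding.

direction_of <- function(S) {
  # S: states submatrix genes x members; direction per the set semantics
  all_over <- rowSums(S == ST_OVER) == ncol(S)
  all_under <- rowSums(S == ST_UNDER) == ncol(S)
  all_absent <- rowSums(S == ST_ABSENT) == ncol(S)
  dir <- rep("mixed", nrow(S))
  dir[all_over] <- "over"
  dir[all_under] <- "under"
  dir[all_absent] <- "absent"
  dir
}

#' Synapomorphies of a clade
#'
#' Returns the genes with a derived state (binary 1) in every member of the
#' clade — the shared derived expression states that circumscribe it — with
#' a direction label per gene: `over` (derived_over in all members), `under`
#' (derived_under in all), `absent` (derived_absent in all), `mixed`
#' otherwise.
#'
#' @param polarity a `polarity_matrix`.
#' @param members character vector of sample ids (at least one).
#' @return object of class `synapomorphy_set`: `members`, `genes`, named
#'   `direction` vector.
#' @export
clade_synapomorphies <- function(polarity, members) {
  members <- as.character(members)
  if (!length(members)) stop("clade needs at least one member")
  unknown <- setdiff(members, colnames(polarity$states))
  if (length(unknown))
    stop("unknown sample id(s): ", paste(unknown, collapse = ", "))
  S <- polarity$states[, members, drop = FALSE]
  shared <- rowSums(S != ST_ANC) == length(members)
  genes <- rownames(S)[shared]
  dir <- direction_of(S[shared, , drop = FALSE])
  structure(list(members = sort(members), genes = genes,
                 direction = setNames(dir, genes)),
            class = "synapomorphy_set")
}

#' @export
print.synapomorphy_set <- function(x, ...) {
  cat(sprintf("synapomorphy_set: %d genes shared derived by {%s}\n",
              length(x$genes), paste(x$members, collapse = ", ")))
  invisible(x)
}

#' Partition a synapomorphy set by direction
#'
#' @param synset a `synapomorphy_set`.
#' @return named integer vector with counts `over`, `under`, `mixed`,
#'   `absent`; the counts sum to the number of genes in the set.
#' @export
direction_partition <- function(synset) {
  stopifnot(inherits(synset, "synapomorphy_set"))
  out <- c(over = 0L, under = 0L, mixed = 0L, absent = 0L)
  tab <- table(synset$direction)
  out[names(tab)] <- as.integer(tab)
  out
}

#' Annotate a cladogram with additive synapomorphy counts
#'
#' For every node of a rooted cladogram computes the clade's shared-derived
#' gene set, the *additional* synapomorphies (shared-derived genes not
#' already counted at any ancestor node — by nestedness this is the set
#' difference against the parent clade's shared-derived set), and the
#' cumulative count, which equals the sum of additional counts along the
#' root-to-node path.
#'
#' @param tree rooted `phylo` over analyzed samples (polytomies allowed).
#' @param polarity a `polarity_matrix`.
#' @return object of class `annotated_cladogram`: the tree (internal nodes
#'   labelled `N<id>`), a per-node data.frame `nodes`, and `gene_sets`, a
#'   per-node list with the additional genes and their directions.
#' @export
annotate_cladogram <- function(tree, polarity) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("annotate_cladogram needs a rooted tree")
  missing <- setdiff(tree$tip.label, colnames(polarity$states))
  if (length(missing))
    stop("leaf/leaves absent from the polarity matrix: ",
         paste(missing, collapse = ", "))
  ntip <- length(tree$tip.label)
  nmax <- ntip + tree$Nnode
  members <- node_members(tree)
  parent <- integer(nmax)
  for (i in seq_len(nrow(tree$edge)))
    parent[tree$edge[i, 2]] <- tree$edge[i, 1]
  syn <- lapply(seq_len(nmax), function(v)
    clade_synapomorphies(polarity, members[[v]]))
  root <- ntip + 1L
  # preorder so parents precede children
  ord <- root
  repeat {
    nxt <- tree$edge[tree$edge[, 1] %in% ord, 2]
    nxt <- setdiff(nxt, ord)
    if (!length(nxt)) break
    ord <- c(ord, nxt)
  }
  rows <- lapply(ord, function(v) {
    genes <- syn[[v]]$genes
    add <- if (v == root) genes else setdiff(genes, syn[[parent[v]]]$genes)
    data.frame(node = v,
               node_id = if (v <= ntip) tree$tip.label[v] else paste0("N", v),
               type = if (v <= ntip) "leaf" else "clade",
               n_members = length(members[[v]]),
               members = paste(members[[v]], collapse = ";"),
               n_additional = length(add),
               n_cumulative = length(genes))
  })
  nodes <- do.call(rbind, rows)
  gene_sets <- lapply(ord, function(v) {
    genes <- syn[[v]]$genes
    add <- if (v == root) genes else setdiff(genes, syn[[parent[v]]]$genes)
    list(additional = add, direction = syn[[v]]$direction[add],
         shared = genes)
  })
  names(gene_sets) <- nodes$node_id
  tree$node.label <- paste0("N", seq(ntip + 1L, nmax))
  structure(list(tree = tree, nodes = nodes, gene_sets = gene_sets),
            class = "annotated_cladogram")
}

#' @export
print.annotated_cladogram <- function(x, ...) {
  cat("annotated_cladogram over", sum(x$nodes$type == "leaf"), "samples\n")
  cl <- x$nodes[x$nodes$type == "clade", ]
  for (i in seq_len(nrow(cl)))
    cat(sprintf("  %s (%d members): +%d additional, %d cumulative\n",
                cl$node_id[i], cl$n_members[i], cl$n_additional[i],
                cl$n_cumulative[i]))
  invisible(x)
}

#' Map character changes onto tree branches
#'
#' Computes one minimum-change ancestral reconstruction per character (ties
#' resolved toward the ancestral state nearer the root) and returns the
#' per-branch gain and loss lists; the total number of mapped changes equals
#' [tree_length()] for the same model. Branches are identified by their
#' child node; the root's implicit branch from the all-ancestral ancestor is
#' `"stem"`.
#'
#' @param tree rooted binary `phylo`.
#' @param polarity a `polarity_matrix`.
#' @param model `"wagner"` or `"camin_sokal"`.
#' @return list with `changes` (data.frame `branch, gene_id, change`) and
#'   `total`.
#' @export
fitch_map_changes <- function(tree, polarity,
                              model = c("wagner", "camin_sokal")) {
  model <- match.arg(model)
  if (!ape::is.rooted(tree)) stop("fitch_map_changes needs a rooted tree")
  lr <- as_lr(tree)
  binary <- binary_view(polarity)
  missing <- setdiff(tree$tip.label, colnames(binary))
  if (length(missing))
    stop("leaf/leaves absent from the polarity matrix: ",
         paste(missing, collapse = ", "))
  B <- t(binary[, tree$tip.label, drop = FALSE])  # tips x genes, 0/1
  ng <- ncol(B)
  nmax <- lr$next_id - 1L
  genes <- colnames(B)

  state <- matrix(NA_integer_, nrow = nmax, ncol = ng)
  if (model == "wagner") {
    D <- matrix(0L, nrow = nmax, ncol = ng)  # Fitch state sets as bitmasks
    post <- integer(0)
    rec <- function(v) {
      if (lr$lch[v] == 0L) { D[v, ] <<- B[v, ] + 1L; return(invisible()) }
      rec(lr$lch[v]); rec(lr$rch[v])
      x <- bitwAnd(D[lr$lch[v], ], D[lr$rch[v], ])
      z <- x == 0L
      x[z] <- bitwOr(D[lr$lch[v], z], D[lr$rch[v], z])
      D[v, ] <<- x
      post <<- c(post, v)
    }
    rec(lr$root)
    # up-pass: keep the parent's (more ancestral) state whenever allowed
    state[lr$root, ] <- ifelse(bitwAnd(D[lr$root, ], 1L) > 0L, 0L, 1L)
    for (v in rev(post)) {
      for (ch in c(lr$lch[v], lr$rch[v])) {
        ps <- state[v, ]
        want <- ifelse(ps == 0L, 1L, 2L)
        state[ch, ] <- ifelse(bitwAnd(D[ch, ], want) > 0L, ps, D[ch, ] - 1L)
      }
    }
  } else {
    # irreversible: a node is derived iff its whole leaf set is derived
    rec <- function(v) {
      if (lr$lch[v] == 0L) { state[v, ] <<- B[v, ]; return(invisible()) }
      rec(lr$lch[v]); rec(lr$rch[v])
      state[v, ] <<- state[lr$lch[v], ] * state[lr$rch[v], ]
    }
    rec(lr$root)
  }

  edges <- which(lr$par != 0L)
  chunks <- lapply(edges, function(v) {
    p <- lr$par[v]
    gain <- state[p, ] == 0L & state[v, ] == 1L
    loss <- state[p, ] == 1L & state[v, ] == 0L
    if (!any(gain) && !any(loss)) return(NULL)
    branch <- if (v <= lr$ntip) lr$labels[v] else paste0("N", v)
    data.frame(branch = branch,
               gene_id = c(genes[gain], genes[loss]),
               change = c(rep("gain", sum(gain)), rep("loss", sum(loss))))
  })
  stem_gain <- state[lr$root, ] == 1L
  if (any(stem_gain))
    chunks <- c(chunks, list(data.frame(branch = "stem",
                                        gene_id = genes[stem_gain],
                                        change = "gain")))
  changes <- do.call(rbind, chunks)
  if (is.null(changes))
    changes <- data.frame(branch = character(), gene_id = character(),
                          change = character())
  list(changes = changes, total = nrow(changes))
}

#' Three-state heat-map coding
#'
#' Collapses polarity states to `over`, `under`, `unchanged` (the
#' `derived_absent` state displays as `unchanged`) for the requested genes
#' and samples, in the requested order, suitable for alignment against a
#' cladogram leaf order.
#'
#' @param polarity a `polarity_matrix`.
#' @param genes,samples identifiers to include, in output order.
#' @return character matrix of class `heatmap_codes`.
#' @export
heatmap_codes <- function(polarity, genes, samples) {
  unknown <- setdiff(genes, rownames(polarity$states))
  if (length(unknown))
    stop("unknown gene id(s): ", paste(unknown, collapse = ", "))
  unknown <- setdiff(samples, colnames(polarity$states))
  if (length(unknown))
    stop("unknown sample id(s): ", paste(unknown, collapse = ", "))
  S <- polarity$states[genes, samples, drop = FALSE]
  m <- matrix(c("unchanged", "over", "under", "unchanged")[S + 1L],
              nrow = length(genes), dimnames = list(genes, samples))
  structure(m, class = c("heatmap_codes", class(m)))
}

#' Plot heat-map codes
#'
#' Renders the three-state coding as a red (over) / yellow (under) /
#' green (unchanged) image, genes in rows.
#' @param x a `heatmap_codes` matrix.
#' @param ... passed to [graphics::image()].
#' @export
plot.heatmap_codes <- function(x, ...) {
  num <- matrix(match(unclass(x), c("unchanged", "over", "under")),
                nrow = nrow(x))
  graphics::image(seq_len(ncol(x)), seq_len(nrow(x)), t(num[rev(seq_len(nrow(x))), , drop = FALSE]),
                  col = c("#2ca02c", "#d62728", "#e6c700"), zlim = c(1, 3),
                  axes = FALSE, xlab = "", ylab = "", ...)
  graphics::axis(1, at = seq_len(ncol(x)), labels = colnames(x), las = 2,
                 cex.axis = 0.7, tick = FALSE)
  graphics::axis(2, at = seq_len(nrow(x)), labels = rev(rownames(x)), las = 2,
                 cex.axis = 0.7, tick = FALSE)
  invisible(x)
}

#' Write the per-node synapomorphy report
#' @param annotated an `annotated_cladogram`.
#' @param nodes_path TSV for per-node counts; `genes_path` TSV for the
#'   per-node additional gene lists with directions.
#' @param genes_path see above.
#' @export
write_synapomorphy_report <- function(annotated, nodes_path, genes_path) {
  nd <- annotated$nodes[, c("node_id", "type", "n_members", "members",
                            "n_additional", "n_cumulative")]
  write.table(nd, nodes_path, sep = "\t", quote = FALSE, row.names = FALSE)
  gl <- do.call(rbind, lapply(names(annotated$gene_sets), function(nid) {
    gs <- annotated$gene_sets[[nid]]
    if (!length(gs$additional)) return(NULL)
    data.frame(node_id = nid, gene_id = gs$additional,
               direction = unname(gs$direction))
  }))
  if (is.null(gl))
    gl <- data.frame(node_id = character(), gene_id = character(),
                     direction = character())
  write.table(gl, genes_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(nodes_path)
}
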