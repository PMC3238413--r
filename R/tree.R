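# Rooted-tree utilities shared by the search, mapping and evaluation code.
# Trees are ape "phylo" objects; searches additionally use a light
# left/right-child array representation ("lr") mirroring the C++ scorer.

# Convert a rooted binary phylo to child arrays. Node ids are ape ids:
# tips 1..ntip (in tip.label order), root ntip+1.
as_lr <- function(phy, strict_binary = TRUE) {
  if (!inherits(phy, "phylo")) stop("not a phylo object")
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  ntip <- length(phy$tip.label)
  nmax <- ntip + phy$Nnode
  lch <- integer(nmax)
  rch <- integer(nmax)
  par <- integer(nmax)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]; c <- phy$edge[i, 2]
    par[c] <- p
    if (lch[p] == 0L) lch[p] <- c
    else if (rch[p] == 0L) rch[p] <- c
    else if (strict_binary)
      stop("tree has a polytomy; a binary tree is required")
  }
  list(lch = lch, rch = rch, par = par, root = ntip + 1L, ntip = ntip,
       labels = phy$tip.label, next_id = nmax + 1L)
}

# Newick serialization of an lr tree; canonical = TRUE sorts sibling subtree
# strings so topologically identical trees serialize identically.
lr_newick <- function(lr, canonical = FALSE) {
  rec <- function(v) {
    if (lr$lch[v] == 0L) return(lr$labels[v])
    a <- rec(lr$lch[v]); b <- rec(lr$rch[v])
    if (canonical && b < a) { tmp <- a; a <- b; b <- tmp }
    paste0("(", a, ",", b, ")")
  }
  paste0(rec(lr$root), ";")
}

lr_to_phylo <- function(lr, canonical = TRUE) {
  ape::read.tree(text = lr_newick(lr, canonical = canonical))
}

# Members (tip labels) below every node, indexed by ape node id.
node_members <- function(phy) {
  ntip <- length(phy$tip.label)
  nmax <- ntip + phy$Nnode
  kids <- vector("list", nmax)
  for (i in seq_len(nrow(phy$edge)))
    kids[[phy$edge[i, 1]]] <- c(kids[[phy$edge[i, 1]]], phy$edge[i, 2])
  members <- vector("list", nmax)
  rec <- function(v) {
    if (v <= ntip) members[[v]] <<- phy$tip.label[v]
    else members[[v]] <<- sort(unlist(lapply(kids[[v]], rec)))
    members[[v]]
  }
  rec(ntip + 1L)
  members
}

clade_key <- function(members) paste(sort(members), collapse = ",")

# Canonical key of the bipartition {clade, complement}; the two child clades
# of the root are complements and collapse to one key.
split_pair_key <- function(members, all_leaves) {
  a <- clade_key(members)
  b <- clade_key(setdiff(all_leaves, members))
  if (a < b) paste(a, b, sep = " | ") else paste(b, a, sep = " | ")
}

# Bipartition keys of all non-root internal nodes.
tree_split_keys <- function(phy) {
  ntip <- length(phy$tip.label)
  members <- node_members(phy)
  ids <- setdiff(seq(ntip + 1L, ntip + phy$Nnode), ntip + 1L)
  unique(vapply(ids, function(v) split_pair_key(members[[v]], phy$tip.label),
                ""))
}

#' Robinson-Foulds distance between two rooted cladograms
#'
#' Size of the symmetric difference between the two trees' sets of
#' nontrivial clades, with each clade canonicalized to the bipartition
#' `{clade, complement}` it induces (so the two complementary child clades
#' of a root count once). Identical trees give 0; rooted
#' `((A,B),(C,D))` versus `((A,C),(B,D))` gives 2.
#'
#' @param t1,t2 rooted `phylo` objects over the same leaf set.
#' @return non-negative integer.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets")
  k1 <- tree_split_keys(t1)
  k2 <- tree_split_keys(t2)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

# Build a phylo from a laminar family of clades (character-vector members)
# over `leaves`; clades need not include singletons or the full set.
tree_from_clades <- function(clades, leaves) {
  keys <- unique(vapply(clades, clade_key, ""))
  clades <- clades[!duplicated(vapply(clades, clade_key, ""))]
  clades <- clades[order(-lengths(clades))]
  build <- function(M) {
    inside <- clades[vapply(clades, function(cl)
      length(cl) < length(M) && all(cl %in% M), TRUE)]
    maximal <- inside[vapply(seq_along(inside), function(i) {
      !any(vapply(seq_along(inside), function(j)
        j != i && length(inside[[j]]) > length(inside[[i]]) &&
          all(inside[[i]] %in% inside[[j]]), TRUE))
    }, TRUE)]
    parts <- vapply(maximal, function(cl)
      if (length(cl) == 1) cl else build(cl), "")
    rest <- setdiff(M, unlist(maximal))
    paste0("(", paste(c(parts, rest), collapse = ","), ")")
  }
  ape::read.tree(text = paste0(build(sort(leaves)), ";"))
}

#' Strict consensus of a set of rooted trees
#'
#' Returns the tree containing exactly the clades present in every input
#' tree; the result may be non-binary.
#'
#' @param trees a `tree_set` (see [heuristic_search()]) or a list of rooted
#'   `phylo` objects with identical leaf sets.
#' @return a rooted `phylo`, possibly multifurcating.
#' @export
strict_consensus <- function(trees) {
  if (inherits(trees, "tree_set")) trees <- trees$trees
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) stop("no trees given")
  leaves <- sort(trees[[1]]$tip.label)
  for (t in trees)
    if (!setequal(t$tip.label, leaves)) stop("trees have different leaf sets")
  clade_sets <- lapply(trees, function(t) {
    ntip <- length(t$tip.label)
    members <- node_members(t)
    lapply(seq(ntip + 1L, ntip + t$Nnode), function(v) members[[v]])
  })
  key_lists <- lapply(clade_sets, function(cs) vapply(cs, clade_key, ""))
  common_keys <- Reduce(intersect, key_lists)
  common <- clade_sets[[1]][match(common_keys, key_lists[[1]])]
  common <- common[lengths(common) < length(leaves) & lengths(common) > 1]
  tree_from_clades(common, leaves)
}

#' Root a cladogram on the hypothetical all-ancestral outgroup
#'
#' If the tree carries the hypothetical all-zero ancestor leaf `"ROOT0"`,
#' the tree is rooted on the edge leading to it and the ancestor leaf is
#' pruned, leaving a rooted cladogram over samples whose base is the
#' most-ancestral end. Trees that are already rooted (and carry no ancestor
#' leaf) are returned unchanged, so the operation is idempotent.
#'
#' @param tree a `phylo`, either containing the `ROOT0` leaf or already
#'   rooted.
#' @param polarity optional `polarity_matrix`; when given, tree leaves are
#'   checked against its samples.
#' @return rooted `phylo` over the sample leaves.
#' @export
root_cladogram <- function(tree, polarity = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if ("ROOT0" %in% tree$tip.label) {
    rt <- ape::root(tree, outgroup = "ROOT0", resolve.root = TRUE)
    rt <- ape::drop.tip(rt, "ROOT0")
    tree <- rt
  } else if (!ape::is.rooted(tree)) {
    stop("ancestor leaf 'ROOT0' missing and tree is unrooted")
  }
  if (!is.null(polarity)) {
    missing <- setdiff(tree$tip.label, colnames(polarity$states))
    if (length(missing))
      stop("leaf/leaves absent from the polarity matrix: ",
           paste(missing, collapse = ", "))
  }
  tree
}
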