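# Maximum-parsimony tree inference from the binary polarity matrix.
#
# All searches operate on ROOTED binary topologies over the analyzed samples
# with an implicit all-ancestral (state 0) root: this is equivalent to
# appending a hypothetical all-zero ancestor leaf to an unrooted search and
# rooting on its edge, and it fixes the Camin-Sokal root state.

MODEL_CODES <- c(wagner = 0L, camin_sokal = 1L)

# Collapse identical characters (gene columns restricted to `taxa`) into
# weighted site patterns; states coded 1 = ancestral, 2 = derived.
compress_patterns <- function(binary, taxa) {
  missing <- setdiff(taxa, colnames(binary))
  if (length(missing))
    stop("leaf/leaves absent from the polarity matrix: ",
         paste(missing, collapse = ", "))
  M <- binary[, taxa, drop = FALSE]
  key <- do.call(paste0, as.data.frame(M))
  tab <- table(key)
  uniq <- !duplicated(key)
  pat <- M[uniq, , drop = FALSE] + 1L  # 1/2 bitmask coding
  storage.mode(pat) <- "integer"
  list(states = pat, weights = as.numeric(tab[key[uniq]]), taxa = taxa)
}

score_lr <- function(lr, cp, model) {
  score_tree_cpp(lr$lch, lr$rch, lr$root, cp$states, cp$weights,
                 MODEL_CODES[[model]], TRUE)
}

#' Parsimony length of a tree
#'
#' Number of character-state changes the binary polarity matrix requires on
#' the given rooted cladogram. Under `wagner` parsimony changes are
#' reversible and the count is the Fitch small-parsimony length with the
#' root constrained to the all-ancestral state; under `camin_sokal`
#' reversals (1 to 0) are forbidden and the count is the minimum number of
#' gains, the root lineage being fixed ancestral. `derived_absent` counts as
#' the derived state in both models.
#'
#' @param tree rooted `phylo` over samples of `polarity` (a tree carrying
#'   the `ROOT0` ancestor leaf is rooted and pruned first).
#' @param polarity a `polarity_matrix`.
#' @param model `"wagner"` or `"camin_sokal"`.
#' @return integer length.
#' @export
tree_length <- function(tree, polarity, model = c("wagner", "camin_sokal")) {
  model <- match.arg(model)
  tree <- root_cladogram(tree)
  cp <- compress_patterns(binary_view(polarity), tree$tip.label)
  lr <- as_lr(tree)
  as.integer(round(score_lr(lr, cp, model)))
}

make_tree_set <- function(trees, length, model, method, n_opt,
                          seed = NA_integer_, n_starts = NA_integer_) {
  structure(list(trees = trees, length = as.integer(round(length)),
                 model = model, method = method, n_opt = n_opt,
                 seed = seed, n_starts = n_starts),
            class = "tree_set")
}

#' @export
print.tree_set <- function(x, ...) {
  cat(sprintf("tree_set: %d tree(s) retained of %g optimal, length %d (%s, %s)\n",
              length(x$trees), x$n_opt, x$length, x$model, x$method))
  invisible(x)
}

#' Exhaustive most-parsimonious tree search
#'
#' Finds all minimum-length rooted topologies over the analyzed taxa by
#' branch-and-bound enumeration (every topology is either scored or provably
#' excluded, so the full optimum set is returned). Feasible for small taxon
#' sets only.
#'
#' @param polarity a `polarity_matrix`.
#' @param model `"wagner"` or `"camin_sokal"`.
#' @param taxa samples to include as leaves; default all analyzed samples.
#' @param max_taxa refuse larger problems (default 9) and direct the caller
#'   to [heuristic_search()].
#' @param cooptimal_cap maximum number of co-optimal trees retained
#'   (the optimum count is still reported exactly).
#' @return a `tree_set`: rooted `phylo` trees, shared length, model and
#'   search metadata.
#' @export
exhaustive_search <- function(polarity, model = c("wagner", "camin_sokal"),
                              taxa = NULL, max_taxa = 9, cooptimal_cap = 1000) {
  model <- match.arg(model)
  taxa <- taxa %||% colnames(polarity$states)
  n <- length(taxa)
  if (n < 2) stop("need at least 2 taxa")
  if (n > max_taxa)
    stop("taxon count ", n, " exceeds max_taxa = ", max_taxa,
         "; use heuristic_search()")
  cp <- compress_patterns(binary_view(polarity), taxa)
  res <- exhaustive_cpp(cp$states, cp$weights, taxa,
                        MODEL_CODES[[model]], as.integer(cooptimal_cap))
  trees <- lapply(res$newick, function(s) ape::read.tree(text = s))
  # canonical serialization for deterministic ordering and deduplication
  canon <- vapply(trees, function(t) lr_newick(as_lr(t), canonical = TRUE), "")
  o <- order(canon)
  make_tree_set(trees[o], res$length, model, "exhaustive", res$n_opt)
}

# ---- stepwise addition + NNI -----------------------------------------------

lr_start <- function(ntip, labels, t1, t2) {
  nmax <- 2L * ntip - 1L
  lr <- list(lch = integer(nmax), rch = integer(nmax), par = integer(nmax),
             root = ntip + 1L, ntip = ntip, labels = labels,
             next_id = ntip + 2L)
  lr$lch[lr$root] <- t1; lr$rch[lr$root] <- t2
  lr$par[t1] <- lr$root; lr$par[t2] <- lr$root
  lr
}

# insert `tip` above node `v` (v may be the root: a new root is created)
lr_insert <- function(lr, v, tip) {
  m <- lr$next_id
  pv <- lr$par[v]
  if (pv == 0L) lr$root <- m
  else if (lr$lch[pv] == v) lr$lch[pv] <- m
  else lr$rch[pv] <- m
  lr$par[m] <- pv
  lr$lch[m] <- v; lr$rch[m] <- tip
  lr$par[v] <- m; lr$par[tip] <- m
  lr$next_id <- m + 1L
  lr
}

# all rooted SPR neighbors: prune each non-root subtree and regraft it on
# every edge of the remaining tree (including above the root); deterministic
# generation order. The SPR neighborhood strictly contains NNI and is needed
# because parsimony optima can sit in funnels all of whose NNI neighbors are
# several steps longer.
lr_spr_neighbors <- function(lr) {
  out <- list()
  for (v in which(lr$par != 0L)) {
    p <- lr$par[v]
    s <- if (lr$lch[p] == v) lr$rch[p] else lr$lch[p]
    gp <- lr$par[p]
    base <- lr
    if (gp == 0L) {
      base$root <- s
      base$par[s] <- 0L
    } else {
      if (base$lch[gp] == p) base$lch[gp] <- s else base$rch[gp] <- s
      base$par[s] <- gp
    }
    base$par[v] <- 0L
    rem <- integer(0)  # nodes of the remaining tree, preorder
    stack <- base$root
    while (length(stack)) {
      u <- stack[1]; stack <- stack[-1]; rem <- c(rem, u)
      if (base$lch[u] != 0L) stack <- c(stack, base$lch[u], base$rch[u])
    }
    for (u in rem) {
      if (u == s) next  # would recreate the original tree
      nb <- base
      pu <- nb$par[u]
      if (pu == 0L) nb$root <- p
      else if (nb$lch[pu] == u) nb$lch[pu] <- p
      else nb$rch[pu] <- p
      nb$par[p] <- pu
      nb$lch[p] <- u; nb$rch[p] <- v
      nb$par[u] <- p; nb$par[v] <- p
      out[[length(out) + 1L]] <- nb
    }
  }
  out
}

# all rooted NNI neighbors: for every internal non-root node c, swap each of
# its children with its sibling; deterministic generation order
lr_nni_neighbors <- function(lr) {
  out <- list()
  internal <- seq.int(lr$ntip + 1L, lr$next_id - 1L)
  for (cc in setdiff(internal, lr$root)) {
    p <- lr$par[cc]
    s <- if (lr$lch[p] == cc) lr$rch[p] else lr$lch[p]
    for (x in c(lr$lch[cc], lr$rch[cc])) {
      nb <- lr
      if (nb$lch[p] == s) nb$lch[p] <- x else nb$rch[p] <- x
      if (nb$lch[cc] == x) nb$lch[cc] <- s else nb$rch[cc] <- s
      nb$par[x] <- p; nb$par[s] <- cc
      out[[length(out) + 1L]] <- nb
    }
  }
  out
}

stepwise_addition <- function(order, cp, model) {
  ntip <- length(cp$taxa)
  lr <- lr_start(ntip, cp$taxa, order[1], order[2])
  active <- c(order[1], order[2], lr$root)
  for (tip in order[-(1:2)]) {
    best <- NULL; best_s <- Inf
    for (v in active) {  # lowest-index position wins ties
      cand <- lr_insert(lr, v, tip)
      s <- score_lr(cand, cp, model)
      if (s < best_s - 1e-9) { best_s <- s; best <- cand }
    }
    new_internal <- best$next_id - 1L
    lr <- best
    active <- c(active, tip, new_internal)
  }
  lr
}

# Steepest-descent hill climbing over the SPR neighborhood, with a bounded
# number of sideways (equal-length) moves: parsimony surfaces, Camin-Sokal
# ones especially, carry plateaus and funnels plain descent cannot exit.
# Deterministic; cycling is prevented by a visited set of canonical newicks.
spr_climb <- function(lr, cp, model, max_sideways = 5) {
  cur_s <- score_lr(lr, cp, model)
  best <- lr
  best_s <- cur_s
  visited <- lr_newick(lr, canonical = TRUE)
  sideways <- 0L
  repeat {
    nbs <- lr_spr_neighbors(lr)
    if (!length(nbs)) break
    scores <- vapply(nbs, score_lr, 0, cp = cp, model = model)
    k <- which.min(scores)
    if (scores[k] < cur_s - 1e-9) {
      lr <- nbs[[k]]
      cur_s <- scores[k]
      sideways <- 0L
      visited <- c(visited, lr_newick(lr, canonical = TRUE))
      if (cur_s < best_s - 1e-9) { best <- lr; best_s <- cur_s }
      next
    }
    if (sideways >= max_sideways) break
    flat <- which(abs(scores - cur_s) < 1e-9)
    moved <- FALSE
    for (k in flat) {
      key <- lr_newick(nbs[[k]], canonical = TRUE)
      if (!(key %in% visited)) {
        lr <- nbs[[k]]
        visited <- c(visited, key)
        sideways <- sideways + 1L
        moved <- TRUE
        break
      }
    }
    if (!moved) break
  }
  list(lr = best, score = best_s)
}

#' Heuristic most-parsimonious tree search
#'
#' Random-addition-sequence stepwise insertion followed by
#' subtree-prune-and-regraft (SPR) hill climbing with a bounded number of
#' sideways moves, repeated over `n_starts` starts; the best trees found
#' across starts are retained (co-optimal local optima deduplicated, up to
#' `cooptimal_cap`). Deterministic given the seed.
#'
#' @inheritParams exhaustive_search
#' @param seed integer RNG seed for the addition orders.
#' @param n_starts number of random-addition starts.
#' @return a `tree_set`.
#' @export
heuristic_search <- function(polarity, model = c("wagner", "camin_sokal"),
                             seed = 42, n_starts = 20, taxa = NULL,
                             cooptimal_cap = 1000) {
  model <- match.arg(model)
  taxa <- taxa %||% colnames(polarity$states)
  n <- length(taxa)
  if (n < 4) stop("heuristic search needs at least 4 taxa; use exhaustive_search()")
  cp <- compress_patterns(binary_view(polarity), taxa)
  local_seed(seed, {
    best_s <- Inf
    found <- character()
    for (i in seq_len(n_starts)) {
      ord <- sample.int(n)
      res <- spr_climb(stepwise_addition(ord, cp, model), cp, model)
      if (res$score < best_s - 1e-9) {
        best_s <- res$score
        found <- character()
      }
      if (res$score <= best_s + 1e-9) {
        nw <- lr_newick(res$lr, canonical = TRUE)
        if (!(nw %in% found) && length(found) < cooptimal_cap)
          found <- c(found, nw)
      }
    }
    found <- sort(found)
    trees <- lapply(found, function(s) ape::read.tree(text = s))
    make_tree_set(trees, best_s, model, "heuristic", length(found),
                  seed = seed, n_starts = n_starts)
  })
}
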