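# Independent oracles and fixture builders used across the suite.
# The oracles deliberately avoid the package's scoring code paths: lengths
# are obtained by enumerating every assignment of states to internal nodes,
# and topology sets by enumerating every rooted topology.

# Minimum number of changes for one binary character on a rooted binary
# tree, by brute-force enumeration of internal-state assignments. An
# implicit all-ancestral (0) ancestor sits above the root; under
# camin_sokal assignments with any 1 -> 0 edge are discarded.
oracle_char_length <- function(phy, states, model = "wagner") {
  lr <- expclad:::as_lr(phy)
  ntip <- lr$ntip
  internal <- which(lr$lch != 0L)
  n_int <- length(internal)
  tipstate <- unname(states[lr$labels])
  edges <- which(lr$par != 0L)
  best <- Inf
  for (mask in 0:(2^n_int - 1)) {
    s <- integer(lr$next_id - 1L)
    s[seq_len(ntip)] <- tipstate
    s[internal] <- bitwAnd(bitwShiftR(mask, seq_len(n_int) - 1L), 1L)
    valid <- TRUE
    changes <- 0L
    for (v in edges) {
      p <- lr$par[v]
      if (model == "camin_sokal" && s[p] == 1L && s[v] == 0L) {
        valid <- FALSE
        break
      }
      changes <- changes + (s[p] != s[v])
    }
    if (!valid) next
    changes <- changes + (s[lr$root] != 0L)  # implicit ancestor edge
    if (changes < best) best <- changes
  }
  best
}

# Whole-matrix oracle length: sum of per-character minima.
oracle_length <- function(phy, binmat, model = "wagner") {
  sum(vapply(seq_len(nrow(binmat)), function(i)
    oracle_char_length(phy, binmat[i, ], model), 0))
}

# All rooted binary topologies over a label set, as newick strings, by
# recursive leaf insertion over nested lists (independent of the package's
# C++ enumeration).
all_rooted_newicks <- function(labels) {
  insert_all <- function(t, lab) {
    res <- list(list(t, lab))  # new root above t
    if (!is.character(t)) {
      for (i in 1:2) {
        for (sub in insert_all(t[[i]], lab)) {
          tt <- t
          tt[[i]] <- sub
          res <- c(res, list(tt))
        }
      }
    }
    res
  }
  to_newick <- function(t) {
    if (is.character(t)) return(t)
    paste0("(", to_newick(t[[1]]), ",", to_newick(t[[2]]), ")")
  }
  trees <- list(list(labels[1], labels[2]))
  for (lab in labels[-(1:2)]) {
    trees <- do.call(c, lapply(trees, insert_all, lab = lab))
  }
  vapply(trees, function(t) paste0(to_newick(t), ";"), "")
}

canonical_topology <- function(phy) {
  expclad:::lr_newick(expclad:::as_lr(phy), canonical = TRUE)
}

# canonical key of the unrooted topology: the set of nontrivial splits
# (both sides >= 2 leaves), which is invariant under rooting
unrooted_key <- function(phy) {
  keys <- expclad:::tree_split_keys(phy)
  sides <- strsplit(keys, " | ", fixed = TRUE)
  nontrivial <- vapply(sides, function(s) all(grepl(",", s)), TRUE)
  paste(sort(keys[nontrivial]), collapse = " / ")
}

random_binary_polarity <- function(n_taxa, n_chars, p = 0.5) {
  m <- matrix(rbinom(n_taxa * n_chars, 1, p), nrow = n_chars,
              dimnames = list(sprintf("c%03d", seq_len(n_chars)),
                              LETTERS[seq_len(n_taxa)]))
  polarity_from_binary(m)
}

random_rooted_tree <- function(labels) {
  ape::rtopology(length(labels), rooted = TRUE, br = NULL, tip.label = labels)
}

# small expression fixture: 2 outgroup-defined genes over controllable values
make_expression <- function(values, genes = rownames(values),
                            samples = colnames(values)) {
  expression_matrix(values, genes, samples)
}
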