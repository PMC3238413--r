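# Outgroup polarity assessment: coding expression values into ancestral and
# derived states, gene classification, and DEA detection.

row_min <- function(m) do.call(pmin, c(as.data.frame(m), na.rm = TRUE))
row_max <- function(m) do.call(pmax, c(as.data.frame(m), na.rm = TRUE))

#' Outgroup expression profile
#'
#' Computes, per gene, the minimum and maximum expression over the
#' non-missing outgroup values (the "normals' range"), the number of
#' contributing observations, and the effective interval after applying a
#' symmetric fractional tolerance: `[lo - tol*(hi-lo), hi + tol*(hi-lo)]`.
#' Genes observed in fewer than two outgroup samples are flagged unusable.
#'
#' @param matrix an [expression_matrix].
#' @param design a `study_design` built from the same matrix.
#' @param tolerance non-negative fraction of the range width; default 0
#'   (strict min-max interval).
#' @return an object of class `outgroup_profile` with per-gene `lo`, `hi`,
#'   `n_obs`, `usable`, plus the tolerance.
#' @export
outgroup_profile <- function(matrix, design, tolerance = 0) {
  stopifnot(inherits(matrix, "expression_matrix"),
            inherits(design, "study_design"))
  if (tolerance < 0) stop("tolerance must be >= 0")
  X <- matrix$values[, design$outgroup, drop = FALSE]
  n_obs <- rowSums(!is.na(X))
  if (all(n_obs == 0)) stop("empty outgroup: no non-missing outgroup values")
  lo <- row_min(X)
  hi <- row_max(X)
  lo[n_obs == 0] <- NA_real_
  hi[n_obs == 0] <- NA_real_
  structure(list(gene_ids = matrix$gene_ids,
                 lo = setNames(lo, matrix$gene_ids),
                 hi = setNames(hi, matrix$gene_ids),
                 n_obs = setNames(n_obs, matrix$gene_ids),
                 usable = setNames(n_obs >= 2, matrix$gene_ids),
                 tolerance = tolerance),
            class = "outgroup_profile")
}

#' @export
print.outgroup_profile <- function(x, ...) {
  cat(sprintf("outgroup_profile: %d genes (%d usable), tolerance %g\n",
              length(x$gene_ids), sum(x$usable), x$tolerance))
  invisible(x)
}

effective_interval <- function(lo, hi, tolerance) {
  w <- hi - lo
  list(lo = lo - tolerance * w, hi = hi + tolerance * w)
}

# two smallest / two largest per row, with the column of the first extreme,
# used to recompute the outgroup interval with one sample left out
row_extremes <- function(X) {
  Xa <- X; Xa[is.na(Xa)] <- Inf
  jmin <- max.col(-Xa, ties.method = "first")
  min1 <- Xa[cbind(seq_len(nrow(X)), jmin)]
  X2 <- Xa; X2[cbind(seq_len(nrow(X)), jmin)] <- Inf
  min2 <- row_min(X2)
  Xb <- X; Xb[is.na(Xb)] <- -Inf
  jmax <- max.col(Xb, ties.method = "first")
  max1 <- Xb[cbind(seq_len(nrow(X)), jmax)]
  X3 <- Xb; X3[cbind(seq_len(nrow(X)), jmax)] <- -Inf
  max2 <- row_max(X3)
  list(min1 = min1, min2 = min2, max1 = max1, max2 = max2)
}

#' Polarize an expression matrix against the outgroup
#'
#' Codes every analyzed (gene, sample) value as `ancestral` (inside the
#' effective outgroup interval; boundaries inclusive), `derived_over`
#' (above it), `derived_under` (below it), or `derived_absent` (missing
#' ingroup value at a usable gene). Genes flagged unusable in the profile
#' are coded all-ancestral and recorded as excluded.
#'
#' With `leave_one_out = TRUE` (the default) each outgroup sample is coded
#' against the interval recomputed from the remaining outgroup samples, so
#' reference specimens can themselves carry derived states; ingroup samples
#' always use the full profile. Missing outgroup values always code
#' ancestral: reference specimens are not scored for unmeasurability.
#'
#' @param matrix an [expression_matrix].
#' @param profile the [outgroup_profile()] built from the same matrix/design.
#' @param design the `study_design`.
#' @param leave_one_out logical; see above.
#' @return an object of class `polarity_matrix`: integer state matrix
#'   (genes x analyzed samples; 0 ancestral, 1 over, 2 under, 3 absent),
#'   the design echo, and the ids of excluded genes.
#' @export
polarize <- function(matrix, profile, design, leave_one_out = TRUE) {
  stopifnot(inherits(matrix, "expression_matrix"),
            inherits(profile, "outgroup_profile"),
            inherits(design, "study_design"))
  if (!identical(profile$gene_ids, matrix$gene_ids))
    stop("profile was not built from this matrix")
  analyzed <- intersect(matrix$sample_ids, c(design$outgroup, design$ingroup))
  ng <- length(matrix$gene_ids)
  states <- matrix(ST_ANC, nrow = ng, ncol = length(analyzed),
                   dimnames = list(matrix$gene_ids, analyzed))
  usable <- profile$usable
  tol <- profile$tolerance
  eff <- effective_interval(profile$lo, profile$hi, tol)

  ing <- intersect(analyzed, design$ingroup)
  V <- matrix$values[, ing, drop = FALSE]
  s <- matrix(ST_ANC, nrow = ng, ncol = length(ing))
  s[V > eff$hi] <- ST_OVER
  s[V < eff$lo] <- ST_UNDER
  s[is.na(V)] <- ST_ABSENT
  s[!usable, ] <- ST_ANC
  states[, ing] <- s

  outg <- intersect(analyzed, design$outgroup)
  if (leave_one_out && length(outg)) {
    X <- matrix$values[, design$outgroup, drop = FALSE]
    ex <- row_extremes(X)
    nmin1 <- rowSums(X == ex$min1, na.rm = TRUE)
    nmax1 <- rowSums(X == ex$max1, na.rm = TRUE)
    for (j in outg) {
      x <- matrix$values[, j]
      n_wo <- profile$n_obs - !is.na(x)
      lo_wo <- ifelse(!is.na(x) & x == ex$min1 & nmin1 == 1, ex$min2, ex$min1)
      hi_wo <- ifelse(!is.na(x) & x == ex$max1 & nmax1 == 1, ex$max2, ex$max1)
      e <- effective_interval(lo_wo, hi_wo, tol)
      sj <- rep(ST_ANC, ng)
      ok <- usable & !is.na(x) & n_wo >= 1
      sj[ok & x > e$hi] <- ST_OVER
      sj[ok & x < e$lo] <- ST_UNDER
      states[, j] <- sj
    }
  }
  # with leave_one_out off, every usable outgroup value lies inside the
  # interval it helped define: states stay ancestral (nothing to compute)

  structure(list(states = states,
                 outgroup = outg, ingroup = ing,
                 excluded_genes = matrix$gene_ids[!usable],
                 tolerance = tol, leave_one_out = leave_one_out),
            class = "polarity_matrix")
}

#' @export
print.polarity_matrix <- function(x, ...) {
  cat(sprintf(paste0("polarity_matrix: %d genes x %d samples ",
                     "(%d outgroup, %d ingroup), %d derived calls, ",
                     "%d excluded genes\n"),
              nrow(x$states), ncol(x$states), length(x$outgroup),
              length(x$ingroup), sum(x$states != ST_ANC),
              length(x$excluded_genes)))
  invisible(x)
}

#' Binary (0/1) view of a polarity matrix
#'
#' Ancestral maps to 0; every derived state (over, under, absent) maps to 1.
#' @param polarity a `polarity_matrix`.
#' @return integer 0/1 matrix with the same dimnames.
#' @export
binary_view <- function(polarity) {
  stopifnot(inherits(polarity, "polarity_matrix"))
  b <- (polarity$states != ST_ANC) + 0L
  dimnames(b) <- dimnames(polarity$states)
  b
}

#' Construct a polarity matrix from a precomputed binary coding
#'
#' Convenience constructor for matrices already coded 0/1 (1 is stored as
#' `derived_over`). Used for worked examples and for users with their own
#' coding.
#'
#' @param binary integer 0/1 matrix, genes x samples, with dimnames.
#' @param outgroup,ingroup sample id partitions; by default all samples are
#'   ingroup.
#' @export
polarity_from_binary <- function(binary, outgroup = character(),
                                 ingroup = setdiff(colnames(binary), outgroup)) {
  binary <- as.matrix(binary)
  if (is.null(rownames(binary)))
    rownames(binary) <- sprintf("c%d", seq_len(nrow(binary)))
  if (is.null(colnames(binary))) stop("binary matrix needs sample names")
  if (!all(binary %in% c(0, 1))) stop("binary matrix must contain only 0/1")
  states <- matrix(ifelse(binary == 1, ST_OVER, ST_ANC), nrow = nrow(binary),
                   dimnames = dimnames(binary))
  structure(list(states = states, outgroup = outgroup, ingroup = ingroup,
                 excluded_genes = character(), tolerance = 0,
                 leave_one_out = FALSE),
            class = "polarity_matrix")
}

#' Classify genes by their ingroup polarity pattern
#'
#' Assigns each gene exactly one of five classes over the ingroup samples:
#' `unchanged` (no derived calls), `overexpressed` (only over calls),
#' `underexpressed` (only under calls), `dea` (at least one over and one
#' under call: dichotomously expressed asynchronous), `unmeasurable` (only
#' absent calls).
#'
#' @param polarity a `polarity_matrix`.
#' @param design optional `study_design`; defaults to the design the
#'   polarity matrix carries.
#' @return data.frame `gene_id, class, n_over, n_under, n_ancestral,
#'   n_absent`.
#' @export
classify_genes <- function(polarity, design = NULL) {
  stopifnot(inherits(polarity, "polarity_matrix"))
  ing <- if (is.null(design)) polarity$ingroup else design$ingroup
  if (!length(ing)) stop("no ingroup samples to classify over")
  S <- polarity$states[, ing, drop = FALSE]
  n_over <- rowSums(S == ST_OVER)
  n_under <- rowSums(S == ST_UNDER)
  n_anc <- rowSums(S == ST_ANC)
  n_abs <- rowSums(S == ST_ABSENT)
  cls <- rep("unchanged", nrow(S))
  cls[n_abs >= 1 & n_over == 0 & n_under == 0] <- "unmeasurable"
  cls[n_over >= 1 & n_under == 0] <- "overexpressed"
  cls[n_under >= 1 & n_over == 0] <- "underexpressed"
  cls[n_over >= 1 & n_under >= 1] <- "dea"
  data.frame(gene_id = rownames(S), class = cls, n_over = n_over,
             n_under = n_under, n_ancestral = n_anc, n_absent = n_abs,
             row.names = NULL)
}

#' Detect dichotomously expressed asynchronous (DEA) genes
#'
#' A DEA gene has ingroup expression values both above and below the
#' outgroup range: at least one `derived_over` and one `derived_under` call.
#'
#' @inheritParams classify_genes
#' @return sorted character vector of gene ids.
#' @export
detect_dea <- function(polarity, design = NULL) {
  cls <- classify_genes(polarity, design)
  sort(cls$gene_id[cls$class == "dea"])
}

#' Write a polarity matrix as TSV
#'
#' Cells are coded `0` (ancestral), `O` (over), `U` (under), `A` (absent);
#' with `binary = TRUE` the collapsed 0/1 view is written instead.
#' @param polarity a `polarity_matrix`.
#' @param path output path.
#' @param binary write the 0/1 view.
#' @export
write_polarity <- function(polarity, path, binary = FALSE) {
  m <- if (binary) binary_view(polarity)
       else matrix(c("0", "O", "U", "A")[polarity$states + 1L],
                   nrow = nrow(polarity$states),
                   dimnames = dimnames(polarity$states))
  writeLines(c(paste(c("gene_id", colnames(m)), collapse = "\t"),
               paste(rownames(m), apply(m, 1, paste, collapse = "\t"),
                     sep = "\t")), path)
  invisible(path)
}

#' Read a polarity TSV written by [write_polarity()]
#' @param path file path.
#' @param outgroup,ingroup sample partitions to attach.
#' @export
read_polarity <- function(path, outgroup = character(), ingroup = NULL) {
  lines <- readLines(path, warn = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]][-1]
  rows <- fields[-1]
  m <- matrix(unlist(lapply(rows, `[`, -1), use.names = FALSE),
              nrow = length(rows), byrow = TRUE,
              dimnames = list(vapply(rows, `[`, "", 1), header))
  code <- match(m, c("0", "O", "U", "A")) - 1L
  if (any(is.na(code))) stop("unknown polarity code in ", path)
  states <- matrix(code, nrow = nrow(m), dimnames = dimnames(m))
  structure(list(states = states, outgroup = outgroup,
                 ingroup = ingroup %||% setdiff(header, outgroup),
                 excluded_genes = character(), tolerance = NA_real_,
                 leave_one_out = NA),
            class = "polarity_matrix")
}
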