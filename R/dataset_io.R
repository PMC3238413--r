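# Reading, validating and writing expression matrices and study designs.

#' Construct an expression matrix
#'
#' Bundles a real-valued genes-by-samples matrix with validated row and
#' column identifiers. Missing values are represented as `NA`; all
#' non-missing entries must be finite.
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param gene_ids,sample_ids character vectors of unique identifiers;
#'   default to the dimnames of `values`.
#' @return an object of class `expression_matrix` with elements `values`
#'   (numeric matrix with dimnames), `gene_ids` and `sample_ids`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("gene_ids and sample_ids are required")
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(values) != length(gene_ids) || ncol(values) != length(sample_ids))
    stop("matrix dimensions do not match the id lists")
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup))
    stop("duplicate gene id(s): ", paste(dup, collapse = ", "))
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup))
    stop("duplicate sample id(s): ", paste(dup, collapse = ", "))
  if (any(!is.na(values) & !is.finite(values)))
    stop("non-finite expression values present")
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(values = values, gene_ids = gene_ids,
                 sample_ids = sample_ids),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%d missing cells)\n",
              length(x$gene_ids), length(x$sample_ids), sum(is.na(x$values))))
  invisible(x)
}

unquote_fields <- function(x) gsub('^"|"$', "", x)

parse_table_lines <- function(lines, line_offset, path) {
  # sentinel keeps trailing empty fields, which strsplit would drop
  fields <- lapply(strsplit(paste0(lines, "\t\x01"), "\t", fixed = TRUE),
                   function(x) x[-length(x)])
  header <- unquote_fields(fields[[1]])
  nc <- length(header)
  if (nc < 2) stop("expression table in ", path, " has no sample columns")
  rows <- fields[-1]
  lens <- lengths(rows)
  if (any(lens != nc)) {
    i <- which(lens != nc)[1]
    stop(sprintf("ragged row at line %d of %s: %d fields, expected %d",
                 line_offset + 1 + i, path, lens[i], nc))
  }
  m <- matrix(unquote_fields(unlist(rows, use.names = FALSE)),
              nrow = length(rows), byrow = TRUE)
  gene_ids <- m[, 1]
  toks <- m[, -1, drop = FALSE]
  miss <- tolower(toks) %in% MISSING_TOKENS
  vals <- suppressWarnings(as.numeric(toks))
  bad <- is.na(vals) & !miss
  if (any(bad)) {
    k <- which(bad)[1]
    r <- (k - 1) %% nrow(toks) + 1
    cc <- (k - 1) %/% nrow(toks) + 1
    stop(sprintf("non-numeric value '%s' at line %d, column %d of %s",
                 toks[k], line_offset + 1 + r, cc + 1, path))
  }
  vals[miss] <- NA_real_
  dim(vals) <- dim(toks)
  expression_matrix(vals, gene_ids = gene_ids, sample_ids = header[-1])
}

#' Read an expression table
#'
#' Reads a genes-by-samples expression table from either a plain TSV file
#' (first column gene id, header row sample ids) or the GEO Series Matrix
#' dialect, where the table sits between the `!series_matrix_table_begin`
#' and `!series_matrix_table_end` sentinel lines and other `!`-prefixed
#' metadata lines are ignored (sample titles, when present, are attached as
#' the `"sample_titles"` attribute to help write a design file).
#'
#' Empty strings, `NA` and `null` (case-insensitive) map to the missing
#' marker. Values are used exactly as provided; no transform is applied.
#'
#' @param path file path.
#' @param format `"tsv"` or `"geo_series_matrix"`.
#' @return an [expression_matrix].
#' @export
read_expression_table <- function(path, format = c("tsv", "geo_series_matrix")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "geo_series_matrix") {
    b <- which(trimws(lines) == "!series_matrix_table_begin")
    e <- which(trimws(lines) == "!series_matrix_table_end")
    if (length(b) != 1 || length(e) != 1 || e <= b + 1)
      stop("series-matrix table sentinels not found in ", path)
    em <- parse_table_lines(lines[(b + 1):(e - 1)], line_offset = b, path = path)
    tl <- grep("^!Sample_title", lines, value = TRUE)
    if (length(tl)) {
      titles <- unquote_fields(strsplit(tl[1], "\t", fixed = TRUE)[[1]][-1])
      if (length(titles) == length(em$sample_ids))
        attr(em, "sample_titles") <- setNames(titles, em$sample_ids)
    }
    em
  } else {
    lines <- lines[seq_len(max(which(nzchar(lines))))]
    parse_table_lines(lines, line_offset = 0, path = path)
  }
}

#' Write an expression table
#'
#' Inverse of [read_expression_table()]; numeric values are serialized with
#' full precision so that a write/read round trip reproduces the matrix
#' bit-for-bit.
#'
#' @param em an [expression_matrix].
#' @param path output file path.
#' @param format `"tsv"` or `"geo_series_matrix"`.
#' @export
write_expression_table <- function(em, path,
                                   format = c("tsv", "geo_series_matrix")) {
  format <- match.arg(format)
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))
  header <- if (format == "tsv") {
    paste(c("gene_id", em$sample_ids), collapse = "\t")
  } else {
    paste(c("\"ID_REF\"", paste0('"', em$sample_ids, '"')), collapse = "\t")
  }
  body <- paste(em$gene_ids,
                apply(em$values, 1, function(r) paste(fmt(r), collapse = "\t")),
                sep = "\t")
  if (format == "geo_series_matrix") {
    titles <- attr(em, "sample_titles") %||% setNames(em$sample_ids, em$sample_ids)
    lines <- c("!Series_title\t\"expclad export\"",
               paste(c("!Sample_title", paste0('"', titles[em$sample_ids], '"')),
                     collapse = "\t"),
               "!series_matrix_table_begin", header, body,
               "!series_matrix_table_end")
  } else {
    lines <- c(header, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Build a study design
#'
#' Labels samples as outgroup (reference specimens whose per-gene range
#' defines the ancestral state) or ingroup (specimens under study). Samples
#' of the matrix in neither list are carried as unassigned and excluded from
#' analysis.
#'
#' @param outgroup_ids,ingroup_ids character vectors of sample ids.
#' @param matrix an [expression_matrix].
#' @return an object of class `study_design` with elements `outgroup`,
#'   `ingroup`, `unassigned`.
#' @export
build_design <- function(outgroup_ids, ingroup_ids, matrix) {
  outgroup_ids <- as.character(outgroup_ids)
  ingroup_ids <- as.character(ingroup_ids)
  unknown <- setdiff(c(outgroup_ids, ingroup_ids), matrix$sample_ids)
  if (length(unknown))
    stop("sample id(s) not in the matrix: ", paste(unknown, collapse = ", "))
  overlap <- intersect(outgroup_ids, ingroup_ids)
  if (length(overlap))
    stop("sample id(s) in both outgroup and ingroup: ",
         paste(overlap, collapse = ", "))
  if (length(outgroup_ids) < 2)
    stop("outgroup must contain at least 2 samples (a range needs two values)")
  if (length(ingroup_ids) < 1)
    stop("ingroup is empty")
  structure(list(outgroup = outgroup_ids, ingroup = ingroup_ids,
                 unassigned = setdiff(matrix$sample_ids,
                                      c(outgroup_ids, ingroup_ids))),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("study_design: %d outgroup, %d ingroup, %d unassigned\n",
              length(x$outgroup), length(x$ingroup), length(x$unassigned)))
  invisible(x)
}

#' Read a study-design file
#'
#' Two-column TSV `sample_id<TAB>group` with group one of `outgroup`,
#' `ingroup`, `unassigned`. A header row is detected and skipped.
#'
#' @param path design file path.
#' @param matrix the [expression_matrix] the design refers to.
#' @return a `study_design`.
#' @export
read_design <- function(path, matrix) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 2))
    stop("design file must have exactly two tab-separated columns: ", path)
  df <- data.frame(sample_id = vapply(fields, `[`, "", 1),
                   group = tolower(vapply(fields, `[`, "", 2)))
  if (df$sample_id[1] %in% c("sample_id", "sample")) df <- df[-1, ]
  bad <- setdiff(df$group, c("outgroup", "ingroup", "unassigned"))
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  build_design(df$sample_id[df$group == "outgroup"],
               df$sample_id[df$group == "ingroup"], matrix)
}

#' Write a study-design file
#' @param design a `study_design`.
#' @param path output path.
#' @export
write_design <- function(design, path) {
  df <- rbind(data.frame(sample_id = design$outgroup, group = "outgroup"),
              data.frame(sample_id = design$ingroup, group = "ingroup"),
              if (length(design$unassigned))
                data.frame(sample_id = design$unassigned, group = "unassigned"))
  writeLines(c("sample_id\tgroup", paste(df$sample_id, df$group, sep = "\t")),
             path)
  invisible(path)
}

#' Log2-transform an expression matrix
#'
#' Optional preprocessing step `x -> log2(x + 1)`; off by default throughout
#' the package since polarity coding is scale-free with respect to any
#' monotone transform of both outgroup and ingroup values.
#' @param em an [expression_matrix].
#' @export
log2_transform <- function(em) {
  if (any(em$values < -1, na.rm = TRUE))
    stop("log2(x + 1) undefined for values below -1")
  expression_matrix(log2(em$values + 1), em$gene_ids, em$sample_ids)
}
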