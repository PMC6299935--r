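#' Construct an expression matrix object
#'
#' An `ExpressionMatrix` wraps a numeric genes x samples matrix together with
#' a record of the scale the values live on. Gene identifiers are carried as
#' row names and sample names as column names. Duplicate gene identifiers are
#' tolerated at construction time (they arise naturally from raw uploads and
#' from identifier conversion) and are resolved by
#' [collapse_duplicate_ids()]; duplicate sample names are always an error.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   row and column names set.
#' @param scale_kind one of `"counts"` (non-negative integers),
#'   `"normalized"` (non-negative reals such as CPM) or `"transformed"`
#'   (reals, e.g. log2 scale).
#' @return an object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values,
                              scale_kind = c("counts", "normalized", "transformed")) {
  scale_kind <- match.arg(scale_kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("'values' must have gene ids as row names and sample ids as column names")
  }
  if (ncol(values) < 2L) stop("an expression matrix needs at least 2 samples")
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample names: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  }
  if (any(!is.finite(values))) stop("all expression values must be finite")
  if (scale_kind %in% c("counts", "normalized") && any(values < 0)) {
    stop("negative values are not allowed on the '", scale_kind, "' scale")
  }
  structure(list(values = values, scale_kind = scale_kind),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values), x$scale_kind))
  cat("samples:", paste(utils::head(colnames(x$values), 8), collapse = ", "),
      if (ncol(x$values) > 8) "...\n" else "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Gene and sample identifiers
#' @param x an `ExpressionMatrix`.
#' @return character vector of identifiers.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(x$values)

.detect_delimiter <- function(line) {
  counts <- vapply(c("," = ",", "\t" = "\t", ";" = ";"),
                   function(d) lengths(regmatches(line, gregexpr(d, line, fixed = TRUE))),
                   integer(1))
  if (all(counts == 0L)) stop("could not detect a delimiter (comma, tab or semicolon)")
  names(counts)[which.max(counts)]
}

#' Read a gene-level expression matrix from CSV/TSV
#'
#' The first column must hold gene identifiers; every remaining column is a
#' numeric sample column. The delimiter is auto-detected among comma, tab and
#' semicolon unless given. Duplicate gene-identifier rows are retained
#' (collapse them explicitly with [collapse_duplicate_ids()]); duplicate
#' sample headers are rejected. When all values are non-negative integers the
#' matrix is flagged as raw counts, otherwise as normalized values; pass
#' `scale_kind` to override the guess.
#'
#' @param path path to a delimited text file with a header row.
#' @param delimiter optional single character; auto-detected when `NULL`.
#' @param scale_kind optional override of the counts/normalized guess.
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(path, delimiter = NULL, scale_kind = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !nzchar(first)) stop("empty file: ", path)
  if (is.null(delimiter)) delimiter <- .detect_delimiter(first)
  df <- utils::read.table(path, header = TRUE, sep = delimiter, quote = "\"",
                          check.names = FALSE, colClasses = "character",
                          comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("need at least 2 sample columns, found ", ncol(df) - 1L)
  ids <- trimws(df[[1L]])
  samples <- colnames(df)[-1L]
  if (anyDuplicated(samples)) {
    stop("duplicate sample header: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  vals <- matrix(NA_real_, nrow = nrow(df), ncol = length(samples),
                 dimnames = list(ids, samples))
  for (j in seq_along(samples)) {
    col <- suppressWarnings(as.numeric(df[[j + 1L]]))
    bad <- which(is.na(col) & nzchar(trimws(df[[j + 1L]])))
    if (length(bad) == 0L) bad <- which(is.na(col))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric value '%s' at data row %d, column '%s'",
                   df[[j + 1L]][bad[1L]], bad[1L], samples[j]))
    }
    vals[, j] <- col
  }
  if (is.null(scale_kind)) {
    is_counts <- all(vals >= 0) && all(abs(vals - round(vals)) < 1e-8)
    scale_kind <- if (is_counts) "counts" else "normalized"
  }
  expression_matrix(vals, scale_kind = scale_kind)
}

#' Write an expression matrix as TSV
#'
#' @param x an `ExpressionMatrix`.
#' @param path output path.
#' @param id_column header for the gene-id column.
#' @export
write_expression_matrix <- function(x, path, id_column = "gene_id") {
  stopifnot(inherits(x, "ExpressionMatrix"))
  df <- data.frame(gene_ids(x), x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an experiment design table
#'
#' The first column holds sample names; each remaining column is an
#' experimental factor (genotype, treatment, batch, ...). The sample set must
#' equal the expression matrix's sample set; rows are reordered to the matrix
#' column order. A factor observed at fewer than two levels carries no
#' contrast and is rejected.
#'
#' @param path delimited text file (delimiter auto-detected).
#' @param matrix an `ExpressionMatrix` whose samples the design describes.
#' @param delimiter optional delimiter character.
#' @return a `DesignTable`: a data.frame of factors (as character columns)
#'   with sample ids as row names and a `reference_levels` attribute naming
#'   the first-occurring level of each factor.
#' @export
read_design <- function(path, matrix, delimiter = NULL) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !nzchar(first)) stop("empty design file: ", path)
  if (is.null(delimiter)) delimiter <- .detect_delimiter(first)
  df <- utils::read.table(path, header = TRUE, sep = delimiter, quote = "\"",
                          check.names = FALSE, colClasses = "character",
                          comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("design file needs at least one factor column")
  design_table(stats::setNames(df[-1L], colnames(df)[-1L]),
               sample_ids = trimws(df[[1L]]), matrix = matrix)
}

#' Construct a design table from factor assignments
#'
#' @param factors data.frame (or list) of per-sample factor levels.
#' @param sample_ids sample names, parallel to the rows of `factors`.
#' @param matrix `ExpressionMatrix` to harmonise sample order with.
#' @return a `DesignTable` (see [read_design()]).
#' @export
design_table <- function(factors, sample_ids, matrix) {
  df <- as.data.frame(factors, stringsAsFactors = FALSE, check.names = FALSE)
  if (anyDuplicated(sample_ids)) stop("duplicate sample names in design")
  missing <- setdiff(colnames(matrix$values), sample_ids)
  extra <- setdiff(sample_ids, colnames(matrix$values))
  if (length(missing) > 0L || length(extra) > 0L) {
    stop("design samples must match matrix samples exactly",
         if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; unknown: ", paste(extra, collapse = ", ")))
  }
  rownames(df) <- sample_ids
  df <- df[colnames(matrix$values), , drop = FALSE]
  for (f in colnames(df)) {
    lev <- unique(df[[f]])
    if (length(lev) < 2L) {
      stop("factor '", f, "' has a single level ('", lev, "'); no contrast possible")
    }
  }
  attr(df, "reference_levels") <-
    vapply(df, function(col) unique(col)[1L], character(1))
  class(df) <- c("DesignTable", "data.frame")
  df
}

#' Collapse rows that map to the same gene identifier
#'
#' When several rows map to one target identifier (duplicated probes, or many
#' source ids converting to the same canonical gene), only the row with the
#' largest standard deviation across samples is kept and relabelled to the
#' target id; the rest are dropped. Ties in SD are broken by input order. SD
#' uses the sample (n-1) denominator.
#'
#' @param x an `ExpressionMatrix` (duplicate row ids allowed).
#' @param target_ids character vector, one target id per row; defaults to the
#'   row's own id (collapsing pre-existing duplicates).
#' @return an `ExpressionMatrix` with strictly unique gene ids, rows ordered
#'   by first appearance of each target.
#' @export
collapse_duplicate_ids <- function(x, target_ids = gene_ids(x)) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (length(target_ids) == 0L) stop("empty mapping")
  if (length(target_ids) != nrow(x$values)) {
    stop("'target_ids' must have one entry per row")
  }
  sds <- apply(x$values, 1L, stats::sd)
  keep <- vapply(split(seq_along(target_ids), factor(target_ids, levels = unique(target_ids))),
                 function(idx) idx[which.max(sds[idx])],
                 integer(1))
  out <- x$values[keep, , drop = FALSE]
  rownames(out) <- unique(target_ids)
  expression_matrix(out, scale_kind = x$scale_kind)
}
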