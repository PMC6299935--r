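#' Load a gene identifier mapping table
#'
#' The table is a TSV with at least three columns: source id, canonical
#' (Ensembl-style) id, species; an optional fourth column records the id
#' type (symbol, refseq, ...). Matching downstream is case-insensitive and
#' version-tolerant: a normalised key is derived from each source id by
#' lower-casing and stripping a trailing version suffix (".<digits>").
#'
#' @param path TSV file, no header required (a header line whose first field
#'   is `source_id` is skipped).
#' @return an `IDMappingTable`: a data.frame with columns `source_id`,
#'   `canonical_id`, `species`, `id_type` and the derived `key`.
#' @export
load_mapping_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty mapping table: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0L) {
    stop("malformed mapping line ", bad[1L], ": expected >= 3 tab-separated fields")
  }
  df <- data.frame(
    source_id    = vapply(fields, `[`, character(1), 1L),
    canonical_id = vapply(fields, `[`, character(1), 2L),
    species      = vapply(fields, `[`, character(1), 3L),
    id_type      = vapply(fields, function(f) if (length(f) >= 4L) f[4L] else NA_character_,
                          character(1)),
    stringsAsFactors = FALSE
  )
  if (tolower(df$source_id[1L]) == "source_id") df <- df[-1L, , drop = FALSE]
  df <- unique(df)
  df$key <- normalize_gene_id(df$source_id)
  class(df) <- c("IDMappingTable", "data.frame")
  df
}

#' Normalise a gene identifier for matching
#'
#' Lower-cases and strips a trailing `.<digits>` version suffix, so that
#' `ENSG00000141510.11` and `ensg00000141510` compare equal.
#'
#' @param ids character vector.
#' @return character vector of normalised keys.
#' @export
normalize_gene_id <- function(ids) {
  sub("\\.[0-9]+$", "", tolower(trimws(ids)))
}

#' Detect the most likely species from gene identifiers
#'
#' Each species in the mapping table is scored by the number of distinct
#' query identifiers whose normalised key occurs among that species' source
#' ids; the species are ranked by matched count, ties broken alphabetically.
#'
#' @param query_ids character vector of identifiers (e.g. the row names of an
#'   uploaded matrix).
#' @param table an `IDMappingTable`.
#' @return data.frame with columns `species` and `matched`, best species
#'   first; attribute `no_match` is `TRUE` when no id matched any species.
#' @export
detect_species <- function(query_ids, table) {
  stopifnot(inherits(table, "IDMappingTable"))
  if (length(query_ids) == 0L) stop("empty query")
  keys <- unique(normalize_gene_id(query_ids))
  species <- sort(unique(table$species))
  matched <- vapply(species, function(sp) {
    sum(keys %in% table$key[table$species == sp])
  }, integer(1))
  out <- data.frame(species = species, matched = matched,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$matched, out$species), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "no_match") <- all(out$matched == 0L)
  if (attr(out, "no_match")) {
    warning("no query id matched any species in the mapping table")
  }
  out
}

#' Convert matrix row identifiers to the canonical namespace
#'
#' Each row id is replaced by its canonical id for the chosen species
#' (matching is case-insensitive and version-tolerant). A source id mapping
#' to several canonical ids contributes one row per target. Rows that end up
#' sharing a canonical id are collapsed, keeping the row with the largest
#' standard deviation. Unmatched rows keep their original ids when
#' `keep_unmatched` is set and are dropped otherwise.
#'
#' @param x an `ExpressionMatrix`.
#' @param table an `IDMappingTable`.
#' @param species species whose mappings to use; must occur in `table`.
#' @param keep_unmatched keep rows whose id has no mapping (default `TRUE`).
#' @return list with elements `matrix` (converted `ExpressionMatrix`) and
#'   `report` (matched / unmatched / collapsed counts).
#' @export
convert_ids <- function(x, table, species, keep_unmatched = TRUE) {
  stopifnot(inherits(x, "ExpressionMatrix"), inherits(table, "IDMappingTable"))
  if (!species %in% table$species) stop("unknown species: ", species)
  sub <- table[table$species == species, , drop = FALSE]
  keys <- normalize_gene_id(gene_ids(x))
  hits <- split(sub$canonical_id, sub$key)
  row_targets <- hits[keys]            # list, NULL where unmatched
  matched <- !vapply(row_targets, is.null, logical(1))

  rows <- integer(0)
  targets <- character(0)
  for (i in seq_along(keys)) {
    if (matched[i]) {
      tg <- unique(row_targets[[i]])
      rows <- c(rows, rep.int(i, length(tg)))
      targets <- c(targets, tg)
    } else if (keep_unmatched) {
      rows <- c(rows, i)
      targets <- c(targets, gene_ids(x)[i])
    }
  }
  if (length(rows) == 0L) stop("no rows left after conversion")
  expanded <- expression_matrix(
    `rownames<-`(x$values[rows, , drop = FALSE], make.unique(targets)),
    scale_kind = x$scale_kind
  )
  out <- collapse_duplicate_ids(expanded, target_ids = targets)
  list(matrix = out,
       report = data.frame(
         matched = sum(matched),
         unmatched = sum(!matched),
         collapsed = length(targets) - nrow(out$values),
         rows_in = nrow(x$values),
         rows_out = nrow(out$values)))
}
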