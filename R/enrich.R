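#' Read a gene-set collection from a GMT file
#'
#' GMT is the de facto format for pathway databases: one tab-separated line
#' per set with the set name, a description, then the member gene ids.
#' Duplicate members within a set are stored once; sets with no members are
#' dropped with a warning.
#'
#' @param path GMT file.
#' @param category label for the collection (e.g. "GOBP", "KEGG").
#' @return a `GeneSetCollection`: list with `sets` (named list of character
#'   vectors), `descriptions` and `category`.
#' @export
read_gmt <- function(path, category = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2L)
  if (length(bad) > 0L) {
    stop("malformed GMT line ", bad[1L], ": expected name<TAB>description<TAB>members...")
  }
  nm <- vapply(fields, `[`, character(1), 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate set name: ", paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  desc <- vapply(fields, `[`, character(1), 2L)
  sets <- lapply(fields, function(f) unique(f[-c(1L, 2L)][nzchar(f[-c(1L, 2L)])]))
  names(sets) <- nm
  names(desc) <- nm
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warning("dropping ", sum(empty), " empty set(s): ",
            paste(nm[empty], collapse = ", "))
    sets <- sets[!empty]
    desc <- desc[!empty]
  }
  gene_set_collection(sets, descriptions = desc, category = category)
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors of member gene ids.
#' @param descriptions optional per-set descriptions.
#' @param category collection label.
#' @return a `GeneSetCollection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL, category = "custom") {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("'sets' must have unique names")
  }
  sets <- lapply(sets, unique)
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(list(sets = sets, descriptions = descriptions, category = category),
            class = "GeneSetCollection")
}

#' Write a gene-set collection to GMT
#'
#' @param collection a `GeneSetCollection`.
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection '%s': %d sets (sizes %d-%d)\n", x$category,
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

#' Hypergeometric gene-set enrichment with BH-FDR
#'
#' For each set S, the effective set size is K = |S intersect background|;
#' sets outside the `[size_min, size_max]` window are skipped. With query
#' size n = |query intersect background| (the query is first restricted to
#' the background), overlap k = |S intersect query|, and background size N,
#' the enrichment p-value is the upper hypergeometric tail P(X >= k) for
#' X ~ Hypergeom(N, K, n). Benjamini-Hochberg FDR is computed across all
#' tested sets of the collection; rows are sorted by FDR, then p, then name.
#'
#' The default background is all genes occurring in at least one set of the
#' collection; passing the processed matrix's gene universe (intersected
#' with the collection) is usually the better-calibrated choice.
#'
#' @param query character vector of gene ids (e.g. a DEG list).
#' @param collection a `GeneSetCollection`.
#' @param background character vector of gene ids; `NULL` for all collection
#'   genes.
#' @param size_min,size_max effective-set-size window (defaults 15, 2000).
#' @return an `EnrichmentTable` data.frame: `set`, `k`, `K`, `n`, `N`,
#'   `p_value`, `fdr`, `overlap_genes` (comma-joined).
#' @export
hypergeometric_enrich <- function(query, collection, background = NULL,
                                  size_min = 15L, size_max = 2000L) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  if (is.null(background)) background <- unique(unlist(collection$sets))
  background <- unique(background)
  if (length(background) == 0L) stop("empty background")
  query <- unique(intersect(query, background))
  if (length(query) == 0L) stop("no query gene occurs in the background")
  N <- length(background)
  n <- length(query)
  rows <- lapply(names(collection$sets), function(nm) {
    S <- intersect(collection$sets[[nm]], background)
    K <- length(S)
    if (K < size_min || K > size_max) return(NULL)
    ov <- intersect(S, query)
    k <- length(ov)
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, N = N, p_value = p,
               overlap_genes = paste(ov, collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    out <- data.frame(set = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p_value = numeric(0),
                      fdr = numeric(0), overlap_genes = character(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("EnrichmentTable", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$fdr, out$p_value, out$set),
             c("set", "k", "K", "n", "N", "p_value", "fdr", "overlap_genes")]
  rownames(out) <- NULL
  class(out) <- c("EnrichmentTable", "data.frame")
  out
}

#' Overlap distance between two gene lists
#'
#' Distance between enriched terms, used to summarise redundant GO terms:
#' 1 - |A intersect B| / min(|A|, |B|) (the complement of the overlap
#' coefficient; a term nested inside another has distance 0). Jaccard
#' (division by the union size) is available as an option.
#'
#' @param a,b non-empty character vectors (typically set members restricted
#'   to the query list).
#' @param method `"overlap"` (default) or `"jaccard"`.
#' @return distance in `[0, 1]`.
#' @export
term_overlap_distance <- function(a, b, method = c("overlap", "jaccard")) {
  method <- match.arg(method)
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L || length(b) == 0L) stop("empty gene list")
  inter <- length(intersect(a, b))
  denom <- if (method == "overlap") min(length(a), length(b))
           else length(union(a, b))
  1 - inter / denom
}

#' Summarise enriched terms by gene-overlap tree and network
#'
#' Enriched GO terms are often highly redundant. This builds (i) an
#' average-linkage hierarchical tree of the enriched terms on pairwise
#' overlap distance (members restricted to the query list, as recorded in
#' the enrichment table), and (ii) a term network whose nodes carry
#' -log10(FDR) and overlap counts, with an undirected edge wherever the
#' overlap coefficient reaches `edge_threshold`.
#'
#' @param enriched an `EnrichmentTable` (>= 2 rows for a tree).
#' @param edge_threshold overlap coefficient needed for an edge (default 0.5).
#' @param method distance variant, see [term_overlap_distance()].
#' @return list with `tree` ([stats::hclust] or `NULL` for a single term),
#'   `newick`, `nodes` (data.frame set, neg_log10_fdr, k) and `edges`
#'   (data.frame from, to, overlap).
#' @export
build_term_summary <- function(enriched, edge_threshold = 0.5,
                               method = c("overlap", "jaccard")) {
  stopifnot(inherits(enriched, "EnrichmentTable"))
  method <- match.arg(method)
  if (nrow(enriched) == 0L) stop("no enriched terms to summarise")
  members <- strsplit(enriched$overlap_genes, ",", fixed = TRUE)
  names(members) <- enriched$set
  if (any(lengths(members) == 0L)) {
    stop("term(s) with empty restricted member list: ",
         paste(enriched$set[lengths(members) == 0L], collapse = ", "))
  }
  nodes <- data.frame(set = enriched$set,
                      neg_log10_fdr = -log10(pmax(enriched$fdr, .Machine$double.xmin)),
                      k = enriched$k, stringsAsFactors = FALSE)
  m <- length(members)
  if (m < 2L) {
    return(list(tree = NULL, newick = NULL, nodes = nodes,
                edges = data.frame(from = character(0), to = character(0),
                                   overlap = numeric(0))))
  }
  D <- matrix(0, m, m, dimnames = list(names(members), names(members)))
  edges <- list()
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      d <- term_overlap_distance(members[[i]], members[[j]], method = method)
      D[i, j] <- D[j, i] <- d
      if (1 - d >= edge_threshold) {
        edges[[length(edges) + 1L]] <-
          data.frame(from = names(members)[i], to = names(members)[j],
                     overlap = 1 - d, stringsAsFactors = FALSE)
      }
    }
  }
  tree <- stats::hclust(stats::as.dist(D), method = "average")
  edges <- if (length(edges) > 0L) do.call(rbind, edges) else
    data.frame(from = character(0), to = character(0), overlap = numeric(0))
  list(tree = tree, newick = dendrogram_newick(tree), nodes = nodes,
       edges = edges)
}
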