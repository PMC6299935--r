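#' Select the most variable genes
#'
#' Ranks genes by their standard deviation across all samples and returns
#' the top `n`, in decreasing-SD order; ties keep input order. Restricting
#' exploratory clustering to the top 1000-2500 most variable genes is the
#' usual way to focus heatmaps and k-means on the signal-bearing part of a
#' transformed matrix.
#'
#' @param x an `ExpressionMatrix` (any scale; usually transformed).
#' @param n number of genes to keep (1 <= n <= gene count).
#' @return an `ExpressionMatrix` of the `n` most variable genes.
#' @export
select_top_variable <- function(x, n = 1000L) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (n <= 0L) stop("'n' must be positive")
  if (n > nrow(x$values)) stop("'n' exceeds the number of genes")
  sds <- apply(x$values, 1L, stats::sd)
  ord <- order(sds, decreasing = TRUE)       # stable: ties keep input order
  expression_matrix(x$values[ord[seq_len(n)], , drop = FALSE],
                    scale_kind = x$scale_kind)
}

.cor_safe <- function(m) {
  # correlation between columns; zero-variance columns contribute r = 0
  sds <- apply(m, 2L, stats::sd)
  flat <- sds == 0
  if (any(flat)) {
    warning(sum(flat), " zero-variance item(s); their correlations treated as 0")
  }
  r <- suppressWarnings(stats::cor(m))
  r[is.na(r)] <- 0
  diag(r) <- 1
  r
}

#' Hierarchical clustering of genes or samples
#'
#' Items on the chosen axis are clustered with average linkage on the
#' correlation distance 1 - Pearson r (or Euclidean distance). On the gene
#' axis rows are centred first so the distance reflects expression shape,
#' not level. Zero-variance items get correlation 0 to everything (with a
#' warning) rather than aborting the clustering.
#'
#' @param x an `ExpressionMatrix`.
#' @param axis `"genes"` or `"samples"`.
#' @param distance `"correlation"` (default) or `"euclidean"`.
#' @param linkage linkage method passed to [stats::hclust()] (default
#'   `"average"`).
#' @return an [stats::hclust] dendrogram.
#' @export
hierarchical_cluster <- function(x, axis = c("genes", "samples"),
                                 distance = c("correlation", "euclidean"),
                                 linkage = "average") {
  stopifnot(inherits(x, "ExpressionMatrix"))
  axis <- match.arg(axis)
  distance <- match.arg(distance)
  m <- if (axis == "genes") {
    t(x$values - rowMeans(x$values))   # items become columns, centred
  } else {
    x$values
  }
  if (ncol(m) < 2L) stop("need at least 2 items on the '", axis, "' axis")
  d <- if (distance == "correlation") {
    stats::as.dist(1 - .cor_safe(m))
  } else {
    stats::dist(t(m))
  }
  stats::hclust(d, method = linkage)
}

#' Export a dendrogram as a Newick string
#'
#' @param hc an [stats::hclust] object.
#' @param path optional file to write to.
#' @return the Newick string, invisibly when written to file.
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  tree <- ape::as.phylo(hc)
  txt <- ape::write.tree(tree)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Sample-sample Pearson correlation matrix
#'
#' @param x an `ExpressionMatrix` with >= 2 genes.
#' @return symmetric samples x samples matrix of Pearson r with unit
#'   diagonal; correlations involving a constant sample are `NA`.
#' @export
correlation_matrix <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (nrow(x$values) < 2L) stop("need at least 2 genes")
  sds <- apply(x$values, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("constant sample column(s): ",
            paste(colnames(x$values)[sds == 0], collapse = ", "),
            "; correlations reported as NA")
  }
  r <- suppressWarnings(stats::cor(x$values))
  diag(r) <- 1
  r
}

#' K-means clustering of genes with elbow diagnostics
#'
#' Genes are row-standardised (mean 0, SD 1; constant rows set to 0) so
#' clusters group expression shapes. K-means is run with a fixed seed and
#' multiple restarts for reproducibility. Clusters are relabelled A, B, ...
#' by decreasing size so names are stable across runs. The within-group sum
#' of squares (WSS) curve over k = 1..max(15, k) supports the usual elbow
#' choice of k.
#'
#' @param x an `ExpressionMatrix` (usually top-variance, transformed).
#' @param k number of clusters.
#' @param seed RNG seed.
#' @param nstart number of random restarts (>= 10).
#' @param max_k largest k of the WSS curve (default `max(15, k)`).
#' @return list of class `ClusterAssignment`: `gene_ids`, `cluster_labels`
#'   (letters), `k`, `wss_curve` (data.frame k, wss), `centers`.
#' @export
kmeans_cluster <- function(x, k, seed = 1L, nstart = 10L, max_k = max(15L, k)) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  n <- nrow(x$values)
  if (k > n) stop("'k' exceeds the number of genes")
  z <- t(scale(t(x$values)))
  z[!is.finite(z)] <- 0
  n_distinct <- nrow(unique(z))
  if (k > n_distinct) stop("'k' exceeds the number of distinct gene profiles")
  nstart <- max(10L, nstart)
  # Hartigan-Wong cannot start with as many centres as points; fall back
  fit_km <- function(zz, kk) {
    alg <- if (kk >= nrow(zz)) "Lloyd" else "Hartigan-Wong"
    stats::kmeans(zz, centers = kk, nstart = nstart, iter.max = 100L,
                  algorithm = alg)
  }
  set.seed(seed)
  km <- fit_km(z, k)
  # letter labels by decreasing cluster size (ties: lower original index first)
  ord <- order(-km$size, seq_along(km$size))
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  labels <- LETTERS[relabel[km$cluster]]

  ks <- seq_len(min(max_k, n_distinct))
  wss <- vapply(ks, function(kk) {
    if (kk == 1L) sum(scale(z, scale = FALSE)^2)
    else fit_km(z, kk)$tot.withinss
  }, numeric(1))
  structure(list(gene_ids = gene_ids(x), cluster_labels = labels, k = k,
                 wss_curve = data.frame(k = ks, wss = wss),
                 centers = km$centers, tot_withinss = km$tot.withinss),
            class = "ClusterAssignment")
}

#' Principal component analysis of samples
#'
#' Samples are observations and genes variables; genes are centred, not
#' scaled. Loadings are unit length per component. Sign convention: the
#' largest-magnitude loading of each component is made positive, which fixes
#' the arbitrary sign of every PC deterministically.
#'
#' @param x an `ExpressionMatrix` with >= 2 samples.
#' @return list of class `PCAResult`: `scores` (samples x components),
#'   `loadings` (genes x components), `variance_fraction`.
#' @export
run_pca <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (ncol(x$values) < 2L) stop("need at least 2 samples")
  pc <- stats::prcomp(t(x$values), center = TRUE, scale. = FALSE)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(c) {
    load <- pc$rotation[, c]
    sign(load[which.max(abs(load))]) < 0
  }, logical(1))
  pc$rotation[, flip] <- -pc$rotation[, flip, drop = FALSE]
  pc$x[, flip] <- -pc$x[, flip, drop = FALSE]
  ev <- pc$sdev^2
  structure(list(scores = pc$x, loadings = pc$rotation,
                 variance_fraction = ev / sum(ev)),
            class = "PCAResult")
}
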