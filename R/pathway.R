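#' Parametric gene-set Z-scores (PAGE) on a fold-change vector
#'
#' For a score vector (typically log2 fold-changes) with global mean mu and
#' sample standard deviation sigma, a set whose m members have mean Sm gets
#'
#'     Z = (Sm - mu) * sqrt(m) / sigma
#'
#' i.e. how far the set's mean deviates from the mean over all genes, in
#' standard errors under a normal approximation. The two-tailed p-value
#' comes from the standard normal; BH-FDR is applied across all tested
#' sets. With `abs_mode` the absolute fold-changes are scored instead,
#' which detects pathways perturbed in both directions at once.
#'
#' @param fc named numeric vector of per-gene scores (names are gene ids).
#' @param collection a `GeneSetCollection`.
#' @param abs_mode score `abs(fc)` instead of `fc` (default `FALSE`).
#' @param size_min,size_max effective set-size window after intersecting
#'   with the genes of `fc` (defaults 15, 2000).
#' @return data.frame `set`, `m`, `set_mean`, `z`, `p_value`, `fdr`, sorted
#'   by p-value.
#' @export
page_scores <- function(fc, collection, abs_mode = FALSE,
                        size_min = 15L, size_max = 2000L) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  if (is.null(names(fc))) stop("'fc' must be named by gene id")
  fc <- fc[is.finite(fc)]
  if (length(fc) < 3L) stop("need scores for at least 3 genes")
  v <- if (abs_mode) abs(fc) else fc
  mu <- mean(v)
  sigma <- stats::sd(v)
  if (sigma == 0) stop("zero variance across gene scores")
  rows <- lapply(names(collection$sets), function(nm) {
    members <- intersect(collection$sets[[nm]], names(v))
    m <- length(members)
    if (m < size_min || m > size_max) return(NULL)
    sm <- mean(v[members])
    z <- (sm - mu) * sqrt(m) / sigma
    data.frame(set = nm, m = m, set_mean = sm, z = z,
               p_value = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) stop("no set within the size window")
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$set), ]
  rownames(out) <- NULL
  out
}

#' Per-sample pathway activity matrix (PGSEA-style)
#'
#' Genes are first centred across samples, so each column holds a sample's
#' expression relative to the row mean. The PAGE Z-score is then computed
#' per set within each column, using that column's global mean and sample
#' SD, giving a gene sets x samples matrix of relative pathway activity:
#' red/blue group-contrast heatmap material.
#'
#' @param x an `ExpressionMatrix` on the transformed scale with >= 2
#'   samples.
#' @param collection a `GeneSetCollection`.
#' @param size_min,size_max effective set-size window.
#' @return a `PathwayActivityMatrix`: list with `z` (sets x samples), and
#'   `set_sizes`.
#' @export
pgsea_sample_scores <- function(x, collection, size_min = 15L, size_max = 2000L) {
  stopifnot(inherits(x, "ExpressionMatrix"), inherits(collection, "GeneSetCollection"))
  if (ncol(x$values) < 2L) stop("need at least 2 samples")
  centred <- x$values - rowMeans(x$values)
  genes <- rownames(centred)
  keep <- Filter(function(nm) {
    m <- length(intersect(collection$sets[[nm]], genes))
    m >= size_min && m <= size_max
  }, names(collection$sets))
  if (length(keep) == 0L) stop("no set within the size window")
  mu <- colMeans(centred)
  sigma <- apply(centred, 2L, stats::sd)
  if (any(sigma == 0)) {
    stop("constant sample column(s) after centring: ",
         paste(colnames(centred)[sigma == 0], collapse = ", "))
  }
  z <- t(vapply(keep, function(nm) {
    members <- intersect(collection$sets[[nm]], genes)
    sm <- colMeans(centred[members, , drop = FALSE])
    (sm - mu) * sqrt(length(members)) / sigma
  }, numeric(ncol(centred))))
  dimnames(z) <- list(keep, colnames(x$values))
  sizes <- vapply(keep, function(nm) length(intersect(collection$sets[[nm]], genes)),
                  integer(1))
  structure(list(z = z, set_sizes = sizes), class = "PathwayActivityMatrix")
}

#' Rank pathway activity by group ANOVA and spread
#'
#' Per set, a one-way ANOVA of its per-sample Z-scores across the levels of
#' a design factor asks whether the pathway's activity differs between
#' groups; BH-FDR is computed across sets. Sets passing `fdr < fdr_cut`
#' are then ranked by their spread — the standard deviation of the set's
#' Z across all samples — so the most strongly contrasting pathways come
#' first, and the top `top_k` are returned. A set with identical Z in every
#' sample carries no contrast and gets p = 1.
#'
#' @param activity a `PathwayActivityMatrix`.
#' @param design a `DesignTable`.
#' @param factor_name grouping factor (>= 2 levels, >= 2 samples per level).
#' @param fdr_cut FDR cutoff (default 0.05).
#' @param top_k maximum number of pathways returned (default 30).
#' @return list with `table` (data.frame set, anova_p, fdr, spread, ranked
#'   by spread descending then name), `z` (the corresponding rows of the
#'   activity matrix, same order) and `all_sets` (the unfiltered per-set
#'   statistics, input order).
#' @export
anova_rank_pathways <- function(activity, design, factor_name,
                                fdr_cut = 0.05, top_k = 30L) {
  stopifnot(inherits(activity, "PathwayActivityMatrix"),
            inherits(design, "DesignTable"))
  if (!factor_name %in% colnames(design)) stop("unknown design factor: ", factor_name)
  z <- activity$z
  groups <- factor(design[colnames(z), factor_name])
  if (nlevels(groups) < 2L) stop("factor needs >= 2 levels")
  if (any(table(groups) < 2L)) stop("every level needs >= 2 samples")
  # vectorised one-way ANOVA across the rows of z
  n <- ncol(z)
  gsizes <- as.vector(table(groups))
  gmeans <- t(apply(z, 1L, function(row) tapply(row, groups, mean)))
  grand <- rowMeans(z)
  ss_between <- as.vector(gmeans^2 %*% gsizes) - n * grand^2
  ss_total <- rowSums(z^2) - n * grand^2
  ss_within <- pmax(ss_total - ss_between, 0)
  df1 <- nlevels(groups) - 1L
  df2 <- n - nlevels(groups)
  f <- (ss_between / df1) / (ss_within / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  p[!is.finite(f) | ss_total < 1e-300] <- 1   # constant rows: no contrast
  fdr <- stats::p.adjust(p, method = "BH")
  spread <- apply(z, 1L, stats::sd)
  all_sets <- data.frame(set = rownames(z), anova_p = p, fdr = fdr,
                         spread = spread, stringsAsFactors = FALSE,
                         row.names = NULL)
  tab <- all_sets[all_sets$fdr < fdr_cut, , drop = FALSE]
  tab <- tab[order(-tab$spread, tab$set), , drop = FALSE]
  tab <- utils::head(tab, top_k)
  rownames(tab) <- NULL
  list(table = tab, z = z[tab$set, , drop = FALSE], all_sets = all_sets)
}

#' Pathway analysis of PCA loadings
#'
#' Treats the gene loadings of each principal component as an expression
#' score and asks, per gene set, whether its members' loadings differ from
#' the average loading of all genes (one-sample t-test against the global
#' mean loading). P-values are BH-adjusted within each component; the top
#' `per_pc` sets are reported per component, skipping sets already reported
#' for an earlier component. Labels carry the FDR first, then the component
#' (e.g. `"1.2e-05 PC1"`). Sets with fewer than 3 members among the loaded
#' genes are skipped.
#'
#' @param pca a `PCAResult` with loadings for >= 10 genes.
#' @param collection a `GeneSetCollection`.
#' @param n_components how many leading components to analyse (<= 5).
#' @param per_pc sets reported per component (default 5).
#' @param size_min,size_max set-size window shared with the other
#'   pathway methods.
#' @return data.frame `component`, `set`, `m`, `t_statistic`, `p_value`,
#'   `fdr`, `label`.
#' @export
pca_loading_pathways <- function(pca, collection, n_components = 5L, per_pc = 5L,
                                 size_min = 15L, size_max = 2000L) {
  stopifnot(inherits(pca, "PCAResult"), inherits(collection, "GeneSetCollection"))
  if (nrow(pca$loadings) < 10L) stop("need loadings for at least 10 genes")
  n_components <- min(n_components, 5L, ncol(pca$loadings))
  genes <- rownames(pca$loadings)
  reported <- character(0)
  out <- list()
  for (comp in seq_len(n_components)) {
    load <- pca$loadings[, comp]
    mu0 <- mean(load)
    rows <- lapply(names(collection$sets), function(nm) {
      members <- intersect(collection$sets[[nm]], genes)
      m <- length(members)
      if (m < max(3L, size_min) || m > size_max) return(NULL)
      vals <- load[members]
      if (stats::sd(vals) == 0) {
        tt <- list(statistic = 0, p.value = if (mean(vals) == mu0) 1 else 0)
      } else {
        tt <- stats::t.test(vals, mu = mu0)
      }
      data.frame(component = paste0("PC", comp), set = nm, m = m,
                 t_statistic = as.numeric(tt$statistic),
                 p_value = tt$p.value, stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows) == 0L) next
    tab <- do.call(rbind, rows)
    tab$fdr <- stats::p.adjust(tab$p_value, method = "BH")
    tab <- tab[order(tab$fdr, tab$p_value, tab$set), ]
    tab <- tab[!tab$set %in% reported, , drop = FALSE]
    tab <- utils::head(tab, per_pc)
    reported <- c(reported, tab$set)
    out[[comp]] <- tab
  }
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0L) stop("no set within the size window")
  out$label <- sprintf("%.2g %s", out$fdr, out$component)
  rownames(out) <- NULL
  out
}
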