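#' Welch two-group differential expression on transformed data
#'
#' A deliberately simple two-group test so the pipeline runs end-to-end
#' without an external fit: per gene, the log2 fold-change is the difference
#' of group means on the transformed (log2) scale and the p-value comes from
#' Welch's unequal-variance t-test, with Benjamini-Hochberg FDR across all
#' genes. External results from dedicated count models (DESeq2, limma, ...)
#' can be imported with [read_de_table()] and drive all downstream modules
#' identically.
#'
#' Degenerate genes (zero variance in both groups) get p = 1 when the means
#' agree and p = 0 when they differ.
#'
#' @param x an `ExpressionMatrix` with `scale_kind = "transformed"`.
#' @param design a `DesignTable`.
#' @param factor_name design factor holding the two groups.
#' @param level_a test level (fold-changes are a minus b).
#' @param level_b reference level.
#' @return a `DEResult` data.frame: `gene_id`, `log2_fold_change`,
#'   `t_statistic`, `p_value`, `fdr`.
#' @export
welch_de <- function(x, design, factor_name, level_a, level_b) {
  stopifnot(inherits(x, "ExpressionMatrix"), inherits(design, "DesignTable"))
  if (!factor_name %in% colnames(design)) stop("unknown design factor: ", factor_name)
  lv <- design[[factor_name]]
  for (lev in c(level_a, level_b)) {
    if (!lev %in% lv) stop("level '", lev, "' absent from factor '", factor_name, "'")
  }
  a <- x$values[, lv == level_a, drop = FALSE]
  b <- x$values[, lv == level_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  if (na < 2L || nb < 2L) stop("each level needs >= 2 samples")
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1L, stats::var); vb <- apply(b, 1L, stats::var)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  degen <- se2 == 0
  if (any(degen)) {
    tstat[degen] <- 0
    p[degen] <- ifelse(ma[degen] == mb[degen], 1, 0)
  }
  out <- data.frame(gene_id = gene_ids(x), log2_fold_change = ma - mb,
                    t_statistic = tstat, p_value = p,
                    fdr = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  class(out) <- c("DEResult", "data.frame")
  out
}

#' Import an externally computed differential-expression table
#'
#' Accepts TSV/CSV with columns `gene_id`, `log2FoldChange`, optional
#' `PValue`, and `FDR` (case-insensitive; `padj`/`adj.P.Val` recognised as
#' FDR, `log2FC`/`logFC` as fold-change), so fold-changes and FDR computed
#' by DESeq2, limma, cuffdiff etc. can feed the enrichment and pathway
#' stages.
#'
#' @param path delimited file with a header.
#' @param delimiter optional; auto-detected.
#' @return a `DEResult` data.frame.
#' @export
read_de_table <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delimiter)) delimiter <- .detect_delimiter(readLines(path, n = 1L))
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          check.names = FALSE, stringsAsFactors = FALSE)
  pick <- function(cands, required = TRUE) {
    hit <- which(tolower(colnames(df)) %in% tolower(cands))
    if (length(hit) == 0L) {
      if (required) stop("missing column; expected one of: ",
                         paste(cands, collapse = ", "))
      return(NULL)
    }
    df[[hit[1L]]]
  }
  out <- data.frame(
    gene_id = as.character(pick(c("gene_id", "gene", "id"))),
    log2_fold_change = as.numeric(pick(c("log2FoldChange", "log2FC", "logFC",
                                         "log2_fold_change"))),
    stringsAsFactors = FALSE)
  p <- pick(c("PValue", "p_value", "pvalue", "P.Value"), required = FALSE)
  out$p_value <- if (is.null(p)) NA_real_ else as.numeric(p)
  out$fdr <- as.numeric(pick(c("FDR", "padj", "adj.P.Val", "qvalue")))
  class(out) <- c("DEResult", "data.frame")
  out
}

#' Split a DE result into up- and down-regulated gene lists
#'
#' Uses the conventional strict thresholds: up-regulated when fdr < fdr_cut
#' and fold-change > fc_cut (i.e. 2^log2FC > fc_cut), down-regulated when
#' fdr < fdr_cut and fold-change < 1/fc_cut; everything else is
#' non-significant. A gene with 2^log2FC exactly at the cut is excluded.
#'
#' @param result a `DEResult`.
#' @param fdr_cut FDR threshold (default 0.1).
#' @param fc_cut fold-change threshold, > 1 (default 2).
#' @return list with `up`, `down` (character vectors of gene ids) and
#'   `direction` (per-gene factor up/down/ns, in input order).
#' @export
apply_thresholds <- function(result, fdr_cut = 0.1, fc_cut = 2) {
  stopifnot(inherits(result, "DEResult"))
  if (fc_cut <= 1) stop("'fc_cut' must exceed 1")
  fc <- 2^result$log2_fold_change
  sig <- result$fdr < fdr_cut
  direction <- rep("ns", nrow(result))
  direction[sig & fc > fc_cut] <- "up"
  direction[sig & fc < 1 / fc_cut] <- "down"
  list(up = result$gene_id[direction == "up"],
       down = result$gene_id[direction == "down"],
       direction = factor(direction, levels = c("up", "down", "ns")))
}

#' Venn region counts for two or three gene lists
#'
#' @param lists named list of 2 or 3 character vectors (duplicates within a
#'   list are ignored).
#' @return data.frame with columns `region` (e.g. `"A"`, `"A&B"`) and
#'   `count`, covering every non-empty membership pattern plus all-zero
#'   regions explicitly.
#' @export
venn_counts <- function(lists) {
  if (!is.list(lists) || length(lists) < 2L || length(lists) > 3L) {
    stop("'lists' must be a named list of 2 or 3 gene-id vectors")
  }
  if (is.null(names(lists)) || any(!nzchar(names(lists)))) {
    stop("'lists' must be named")
  }
  if (any(lengths(lists) == 0L)) stop("lists must be non-empty")
  lists <- lapply(lists, unique)
  universe <- unique(unlist(lists))
  member <- vapply(lists, function(l) universe %in% l, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, names(lists)))
  patterns <- expand.grid(rep(list(c(TRUE, FALSE)), length(lists)))[-2^length(lists), ]
  patterns <- patterns[rev(seq_len(nrow(patterns))), , drop = FALSE]
  region <- apply(patterns, 1L, function(p) paste(names(lists)[unlist(p)], collapse = "&"))
  count <- apply(patterns, 1L, function(p) {
    sum(apply(member, 1L, function(m) all(m == unlist(p))))
  })
  data.frame(region = region, count = as.integer(count),
             stringsAsFactors = FALSE, row.names = NULL)
}
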