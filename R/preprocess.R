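#' Default pre-processing configuration
#'
#' Collects the tunables of the pre-processing stage. `cpm_threshold` and
#' `min_samples` control low-expression filtering (keep a gene when its CPM
#' reaches the threshold in at least `min_samples` samples); `pseudocount`
#' is the started-log constant c in log2(CPM + c); `skew_threshold` is the
#' sample skewness above which log-transformation is enforced on
#' non-negative data; `anova_alpha` is the warning level of the library-size
#' QC test.
#'
#' @param cpm_threshold counts-per-million cutoff (default 0.5).
#' @param min_samples minimum number of samples reaching the cutoff (default 1).
#' @param transform `"log_started"` (default) or `"none"`.
#' @param pseudocount started-log constant (default 4).
#' @param skew_threshold skewness above which log is enforced (default 2).
#' @param anova_alpha significance level of the library-size warning (default 0.05).
#' @return a list of class `PreprocessConfig`.
#' @export
preprocess_config <- function(cpm_threshold = 0.5, min_samples = 1L,
                              transform = c("log_started", "none"),
                              pseudocount = 4, skew_threshold = 2,
                              anova_alpha = 0.05) {
  transform <- match.arg(transform)
  stopifnot(cpm_threshold >= 0, min_samples >= 1L, pseudocount > 0,
            anova_alpha > 0, anova_alpha < 1)
  structure(list(cpm_threshold = cpm_threshold,
                 min_samples = as.integer(min_samples),
                 transform = transform, pseudocount = pseudocount,
                 skew_threshold = skew_threshold, anova_alpha = anova_alpha),
            class = "PreprocessConfig")
}

#' Counts per million
#'
#' Scales each column of a counts matrix by its library size (column total)
#' times 1e6, so every column sums to one million.
#'
#' @param x an `ExpressionMatrix` on the counts scale.
#' @return an `ExpressionMatrix` on the normalized scale.
#' @export
compute_cpm <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$scale_kind != "counts") stop("compute_cpm expects a counts matrix")
  libsize <- colSums(x$values)
  zero <- which(libsize == 0)
  if (length(zero) > 0L) {
    stop("zero-total library: ", paste(colnames(x$values)[zero], collapse = ", "))
  }
  expression_matrix(sweep(x$values, 2L, libsize, "/") * 1e6,
                    scale_kind = "normalized")
}

#' Remove genes expressed at very low levels
#'
#' A gene is kept when its CPM reaches `cfg$cpm_threshold` in at least
#' `cfg$min_samples` samples (default: 0.5 CPM in at least one sample). Gene
#' order is preserved. Errors if nothing survives.
#'
#' @param x an `ExpressionMatrix` of counts.
#' @param cfg a [preprocess_config()].
#' @return list with `matrix` (the filtered counts) and `n_removed`.
#' @export
filter_low_expression <- function(x, cfg = preprocess_config()) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$scale_kind != "counts") stop("filtering operates on the counts scale")
  cpm <- compute_cpm(x)$values
  keep <- rowSums(cpm >= cfg$cpm_threshold) >= cfg$min_samples
  if (!any(keep)) {
    stop("no gene passes the filter; consider lowering cpm_threshold (",
         cfg$cpm_threshold, " CPM in >= ", cfg$min_samples, " sample(s))")
  }
  list(matrix = expression_matrix(x$values[keep, , drop = FALSE], "counts"),
       n_removed = sum(!keep))
}

#' Started-log transformation of counts
#'
#' Converts counts to CPM and applies log2(CPM + pseudocount) when
#' `cfg$transform == "log_started"`; with `"none"` the CPM values are
#' returned as-is. Either way the result is flagged `transformed`, the scale
#' downstream analyses consume. The default pseudocount of 4 tames the
#' variance of low counts while leaving high expressors essentially on the
#' log2-CPM scale.
#'
#' @param x an `ExpressionMatrix` of counts.
#' @param cfg a [preprocess_config()].
#' @return an `ExpressionMatrix` with `scale_kind = "transformed"`.
#' @export
transform_counts <- function(x, cfg = preprocess_config()) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$scale_kind != "counts") stop("transform_counts expects a counts matrix")
  cpm <- compute_cpm(x)$values
  vals <- if (cfg$transform == "log_started") log2(cpm + cfg$pseudocount) else cpm
  expression_matrix(vals, scale_kind = "transformed")
}

#' Skewness of the pooled expression distribution
#'
#' Computes the sample skewness (third standardised moment, g1 = m3 /
#' m2^(3/2)) of all matrix values pooled. Highly right-skewed non-negative
#' data is the signature of an untransformed count matrix; when the skewness
#' exceeds the threshold and all values are non-negative, log-transformation
#' should be enforced. A constant matrix has skewness 0 by convention.
#'
#' @param x an `ExpressionMatrix` with at least 10 values.
#' @param skew_threshold flag cutoff (default 2).
#' @return list with `is_skewed` (logical) and `skewness`.
#' @export
detect_skew <- function(x, skew_threshold = 2) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  v <- as.vector(x$values)
  if (length(v) < 10L) stop("need at least 10 values to estimate skewness")
  m <- mean(v)
  m2 <- mean((v - m)^2)
  skew <- if (m2 == 0) 0 else mean((v - m)^3) / m2^1.5
  list(is_skewed = (skew > skew_threshold) && all(v >= 0), skewness = skew)
}

#' Library-size QC by one-way ANOVA
#'
#' Sequencing depth that differs systematically between sample groups is a
#' confounder; this test runs a one-way ANOVA of per-sample total counts
#' across the levels of a design factor and raises a warning flag when the
#' p-value falls below `alpha`.
#'
#' @param x an `ExpressionMatrix` of counts.
#' @param design a `DesignTable`.
#' @param group_factor name of the design factor defining the groups.
#' @param alpha warning level (default 0.05).
#' @return list with `p_value`, `warning` (logical), `f_statistic` and
#'   `group_means` of the library totals.
#' @export
library_size_anova <- function(x, design, group_factor, alpha = 0.05) {
  stopifnot(inherits(x, "ExpressionMatrix"), inherits(design, "DesignTable"))
  if (x$scale_kind != "counts") stop("library sizes are totals of raw counts")
  if (!group_factor %in% colnames(design)) {
    stop("unknown design factor: ", group_factor)
  }
  totals <- colSums(x$values)
  groups <- factor(design[[group_factor]])
  sizes <- table(groups)
  if (any(sizes < 2L)) {
    stop("every level of '", group_factor,
         "' needs >= 2 samples for a finite F statistic")
  }
  fit <- stats::aov(totals ~ groups)
  tab <- summary(fit)[[1L]]
  p <- tab[["Pr(>F)"]][1L]
  list(p_value = p, warning = p < alpha, f_statistic = tab[["F value"]][1L],
       group_means = tapply(totals, groups, mean))
}
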