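#' Assemble a pipeline configuration
#'
#' Collects paths and parameters for [run_pipeline()]. Only `matrix` and
#' `out_dir` are required; stages whose inputs are absent are skipped.
#' The configuration is flat key = value, serialisable with
#' [write_pipeline_config()] and re-readable with [read_pipeline_config()],
#' and every run writes its resolved configuration next to its outputs so a
#' run can be reproduced exactly.
#'
#' @param matrix path to the expression matrix (CSV/TSV).
#' @param out_dir output directory (created if needed).
#' @param design,mapping,gmt,promoters,pwms optional input paths.
#' @param species species for id conversion; `"auto"` detects from the
#'   mapping table.
#' @param cpm_threshold,min_samples,pseudocount,transform pre-processing
#'   parameters, see [preprocess_config()].
#' @param top_genes genes kept for clustering/PCA (default 1000).
#' @param k k-means cluster count (default 4).
#' @param de_factor,de_level_a,de_level_b two-group contrast for the
#'   fallback DE test; default: first design factor, its first two levels.
#' @param group_factor factor for library-size QC and pathway ANOVA;
#'   defaults to `de_factor`.
#' @param fdr_cut,fc_cut DEG thresholds (defaults 0.1 and 2).
#' @param pathway_fdr FDR cutoff of the pathway ANOVA ranking (default 0.05).
#' @param seed RNG seed used by every stochastic step (default 1).
#' @return named list of class `PipelineConfig`.
#' @export
pipeline_config <- function(matrix, out_dir, design = NULL, mapping = NULL,
                            gmt = NULL, promoters = NULL, pwms = NULL,
                            species = "auto", cpm_threshold = 0.5,
                            min_samples = 1L, pseudocount = 4,
                            transform = "log_started", top_genes = 1000L,
                            k = 4L, de_factor = NULL, de_level_a = NULL,
                            de_level_b = NULL, group_factor = NULL,
                            fdr_cut = 0.1, fc_cut = 2, pathway_fdr = 0.05,
                            seed = 1L) {
  cfg <- list(matrix = matrix, out_dir = out_dir, design = design,
              mapping = mapping, gmt = gmt, promoters = promoters,
              pwms = pwms, species = species, cpm_threshold = cpm_threshold,
              min_samples = min_samples, pseudocount = pseudocount,
              transform = transform, top_genes = top_genes, k = k,
              de_factor = de_factor, de_level_a = de_level_a,
              de_level_b = de_level_b, group_factor = group_factor,
              fdr_cut = fdr_cut, fc_cut = fc_cut, pathway_fdr = pathway_fdr,
              seed = seed)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Write / read a flat key = value configuration file
#'
#' @param cfg a `PipelineConfig`.
#' @param path file path.
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  keep <- !vapply(cfg, is.null, logical(1))
  lines <- sprintf("%s = %s", names(cfg)[keep],
                   vapply(cfg[keep], function(v) as.character(v)[1L], character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  cfg <- stats::setNames(lapply(kv, function(x) {
    v <- x[2L]
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  }), vapply(kv, `[`, character(1), 1L))
  do.call(pipeline_config, cfg)
}

.write_stage_tsv <- function(df, path, params = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# exprkit %s",
                     as.character(utils::packageVersion("exprkit"))), con)
  if (length(params) > 0L) {
    writeLines(paste0("# ", paste(names(params), params, sep = "=",
                                  collapse = "; ")), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the analysis pipeline end-to-end
#'
#' Stages run in order: read/convert -> pre-process -> EDA -> DE -> set
#' enrichment -> pathway activity -> motif enrichment. A stage whose inputs
#' are not configured is skipped; a stage that errors is recorded and its
#' dependent stages are skipped, while independent stages still run. Every
#' output TSV starts with comment lines recording the package version and
#' the parameters in force; the resolved configuration is written as
#' `config.txt`. Given the same configuration and seed, reruns are
#' byte-identical.
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, a list with `outputs` (named paths), `skipped`,
#'   `errors` (stage -> condition message) and `ok` (`TRUE` when no stage
#'   errored).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- list(); skipped <- character(0); errors <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }
  write_pipeline_config(cfg, file.path(cfg$out_dir, "config.txt"))

  ## ---- load + optional id conversion -------------------------------------
  em <- run_stage("read_matrix", read_expression_matrix(cfg$matrix))
  if (is.null(em)) {
    return(invisible(list(outputs = outputs, skipped = skipped,
                          errors = errors, ok = FALSE)))
  }
  design <- NULL
  if (!is.null(cfg$design)) {
    design <- run_stage("read_design", read_design(cfg$design, em))
  } else skipped <- c(skipped, "read_design")

  if (!is.null(cfg$mapping)) {
    conv <- run_stage("idmap", {
      tab <- load_mapping_table(cfg$mapping)
      sp <- cfg$species
      if (identical(sp, "auto")) {
        sp <- detect_species(gene_ids(em), tab)$species[1L]
      }
      convert_ids(em, tab, species = sp)
    })
    if (!is.null(conv)) {
      em <- conv$matrix
      outputs$conversion_report <- .write_stage_tsv(
        conv$report, file.path(cfg$out_dir, "conversion_report.tsv"))
    }
  } else {
    em <- collapse_duplicate_ids(em)
    skipped <- c(skipped, "idmap")
  }

  ## ---- pre-processing -----------------------------------------------------
  pcfg <- preprocess_config(cpm_threshold = cfg$cpm_threshold,
                            min_samples = cfg$min_samples,
                            transform = cfg$transform,
                            pseudocount = cfg$pseudocount)
  qc <- list()
  transformed <- run_stage("preprocess", {
    if (em$scale_kind == "counts") {
      filt <- filter_low_expression(em, pcfg)
      qc$genes_removed <- filt$n_removed
      qc$genes_kept <- nrow(filt$matrix$values)
      if (!is.null(design)) {
        gf <- cfg$group_factor
        if (is.null(gf)) gf <- colnames(design)[1L]
        qc_anova <- library_size_anova(filt$matrix, design, gf)
        qc$libsize_anova_p <- qc_anova$p_value
        qc$libsize_warning <- qc_anova$warning
      }
      skew <- detect_skew(filt$matrix)
      qc$skewness <- skew$skewness
      if (skew$is_skewed && pcfg$transform == "none") {
        pcfg$transform <- "log_started"   # enforce log on skewed counts
        qc$log_enforced <- TRUE
      }
      transform_counts(filt$matrix, pcfg)
    } else {
      expression_matrix(em$values, scale_kind = "transformed")
    }
  })
  if (!is.null(transformed) && length(qc) > 0L) {
    outputs$qc_report <- .write_stage_tsv(
      data.frame(metric = names(qc), value = vapply(qc, function(v)
        format(v, digits = 15), character(1))),
      file.path(cfg$out_dir, "qc_report.tsv"),
      params = c(cpm_threshold = cfg$cpm_threshold,
                 min_samples = cfg$min_samples,
                 pseudocount = cfg$pseudocount))
  }
  if (is.null(transformed)) {
    return(invisible(list(outputs = outputs, skipped = skipped,
                          errors = errors, ok = length(errors) == 0L)))
  }
  outputs$transformed_matrix <- file.path(cfg$out_dir, "transformed_matrix.tsv")
  write_expression_matrix(transformed, outputs$transformed_matrix)

  ## ---- EDA ----------------------------------------------------------------
  run_stage("eda", {
    top <- select_top_variable(transformed,
                               min(cfg$top_genes, nrow(transformed$values)))
    hc <- hierarchical_cluster(top, axis = "samples")
    outputs$sample_tree <- file.path(cfg$out_dir, "sample_tree.nwk")
    dendrogram_newick(hc, outputs$sample_tree)
    cm <- correlation_matrix(transformed)
    outputs$correlation_matrix <- .write_stage_tsv(
      data.frame(sample = rownames(cm), cm, check.names = FALSE),
      file.path(cfg$out_dir, "correlation_matrix.tsv"))
    km <- kmeans_cluster(top, k = min(cfg$k, nrow(top$values)), seed = cfg$seed)
    outputs$kmeans_clusters <- .write_stage_tsv(
      data.frame(gene_id = km$gene_ids, cluster = km$cluster_labels),
      file.path(cfg$out_dir, "kmeans_clusters.tsv"), params = c(k = km$k))
    outputs$wss_curve <- .write_stage_tsv(
      km$wss_curve, file.path(cfg$out_dir, "wss_curve.tsv"))
    pca <- run_pca(transformed)
    outputs$pca_scores <- .write_stage_tsv(
      data.frame(sample = rownames(pca$scores), pca$scores, check.names = FALSE),
      file.path(cfg$out_dir, "pca_scores.tsv"))
    outputs$pca_variance <- .write_stage_tsv(
      data.frame(component = paste0("PC", seq_along(pca$variance_fraction)),
                 variance_fraction = pca$variance_fraction),
      file.path(cfg$out_dir, "pca_variance.tsv"))
  })

  ## ---- DE -----------------------------------------------------------------
  de <- NULL
  if (!is.null(design)) {
    de <- run_stage("deg", {
      f <- cfg$de_factor
      if (is.null(f)) f <- colnames(design)[1L]
      levs <- unique(design[[f]])
      la <- if (is.null(cfg$de_level_a)) levs[2L] else cfg$de_level_a
      lb <- if (is.null(cfg$de_level_b)) levs[1L] else cfg$de_level_b
      welch_de(transformed, design, f, la, lb)
    })
    if (!is.null(de)) {
      outputs$de_table <- .write_stage_tsv(
        as.data.frame(de), file.path(cfg$out_dir, "de_table.tsv"),
        params = c(fdr_cut = cfg$fdr_cut, fc_cut = cfg$fc_cut))
    }
  } else skipped <- c(skipped, "deg")

  ## ---- enrichment / pathways / motifs ------------------------------------
  collection <- NULL
  if (!is.null(cfg$gmt)) {
    collection <- run_stage("read_gmt", read_gmt(cfg$gmt))
  } else skipped <- c(skipped, "enrich", "pathway")

  if (!is.null(collection) && !is.null(de)) {
    run_stage("enrich", {
      lists <- apply_thresholds(de, fdr_cut = cfg$fdr_cut, fc_cut = cfg$fc_cut)
      background <- intersect(de$gene_id, unique(unlist(collection$sets)))
      for (dir in c("up", "down")) {
        if (length(intersect(lists[[dir]], background)) == 0L) next
        tab <- hypergeometric_enrich(lists[[dir]], collection,
                                     background = background)
        outputs[[paste0("enrichment_", dir)]] <- .write_stage_tsv(
          as.data.frame(tab),
          file.path(cfg$out_dir, paste0("enrichment_", dir, ".tsv")))
      }
    })
  }
  if (!is.null(collection) && !is.null(de)) {
    run_stage("pathway", {
      fc <- stats::setNames(de$log2_fold_change, de$gene_id)
      pg <- page_scores(fc, collection)
      outputs$page_results <- .write_stage_tsv(
        pg, file.path(cfg$out_dir, "page_results.tsv"))
      if (!is.null(design)) {
        act <- pgsea_sample_scores(transformed, collection)
        gf <- cfg$group_factor
        if (is.null(gf)) gf <- colnames(design)[1L]
        ranked <- anova_rank_pathways(act, design, gf,
                                      fdr_cut = cfg$pathway_fdr)
        outputs$pathway_activity <- .write_stage_tsv(
          data.frame(ranked$table,
                     as.data.frame(ranked$z, check.names = FALSE)),
          file.path(cfg$out_dir, "pathway_activity.tsv"),
          params = c(fdr_cut = cfg$pathway_fdr))
      }
    })
  }
  if (!is.null(cfg$promoters) && !is.null(cfg$pwms)) {
    run_stage("motif", {
      if (is.null(de)) stop("motif enrichment needs a DE gene list")
      proms <- read_promoters_fasta(cfg$promoters)
      pwms <- read_pwms(cfg$pwms)
      scores <- scan_best_scores(proms, pwms)
      lists <- apply_thresholds(de, fdr_cut = cfg$fdr_cut, fc_cut = cfg$fc_cut)
      query <- intersect(c(lists$up, lists$down), rownames(scores))
      tab <- motif_ttest_enrich(scores, query)
      outputs$motif_enrichment <- .write_stage_tsv(
        tab, file.path(cfg$out_dir, "motif_enrichment.tsv"))
    })
  } else skipped <- c(skipped, "motif")

  invisible(list(outputs = outputs, skipped = unique(skipped), errors = errors,
                 ok = length(errors) == 0L))
}
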