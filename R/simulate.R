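#' Simulate a negative-binomial count matrix with planted effects
#'
#' Counts are drawn as NB(mean mu_ig, dispersion phi) with variance
#' mu + mu^2 * phi, the standard RNA-seq regime. Per-gene baseline means are
#' log-normal; a `de_fraction` of genes are differentially expressed, their
#' mean multiplied by `2^effect_log2fc` (up) or `2^-effect_log2fc` (down,
#' half of the DE genes) in every non-reference group. The seed fully
#' determines the output.
#'
#' @param n_genes number of genes (default 2000).
#' @param n_per_group samples per group (default 5).
#' @param n_groups number of groups (default 2; group 1 is the reference).
#' @param dispersion NB dispersion phi (default 0.1).
#' @param mean_log_mu,sd_log_mu meanlog/sdlog of the log-normal gene means
#'   (defaults log(100), 1.5).
#' @param de_fraction fraction of DE genes (default 0.05).
#' @param effect_log2fc planted effect in log2 units (default 2).
#' @param seed RNG seed.
#' @return list with `matrix` (counts `ExpressionMatrix`), `design` (a
#'   `DesignTable` with factor `group`), and `truth` (data.frame `gene_id`,
#'   `is_de`, `direction`, `log2fc`).
#' @export
simulate_counts <- function(n_genes = 2000L, n_per_group = 5L, n_groups = 2L,
                            dispersion = 0.1, mean_log_mu = log(100),
                            sd_log_mu = 1.5, de_fraction = 0.05,
                            effect_log2fc = 2, seed = 1L) {
  stopifnot(n_genes >= 1L, n_per_group >= 1L, n_groups >= 2L, dispersion > 0,
            de_fraction >= 0, de_fraction <= 1)
  set.seed(seed)
  genes <- sprintf("gene%04d", seq_len(n_genes))
  groups <- paste0("grp", seq_len(n_groups))
  samples <- paste0(rep(groups, each = n_per_group), "_s",
                    rep(seq_len(n_per_group), n_groups))
  base_mu <- stats::rlnorm(n_genes, meanlog = mean_log_mu, sdlog = sd_log_mu)

  n_de <- round(de_fraction * n_genes)
  de_idx <- if (n_de > 0L) sort(sample.int(n_genes, n_de)) else integer(0)
  dir_up <- rep(FALSE, n_genes)
  if (n_de > 0L) dir_up[de_idx] <- seq_len(n_de) %% 2L == 1L
  log2fc <- numeric(n_genes)
  log2fc[de_idx] <- ifelse(dir_up[de_idx], effect_log2fc, -effect_log2fc)

  counts <- matrix(0L, nrow = n_genes, ncol = length(samples),
                   dimnames = list(genes, samples))
  size <- 1 / dispersion
  for (g in seq_len(n_groups)) {
    mu <- if (g == 1L) base_mu else base_mu * 2^log2fc
    cols <- (g - 1L) * n_per_group + seq_len(n_per_group)
    for (j in cols) {
      counts[, j] <- stats::rnbinom(n_genes, mu = mu, size = size)
    }
  }
  em <- expression_matrix(counts, scale_kind = "counts")
  design <- design_table(list(group = rep(groups, each = n_per_group)),
                         sample_ids = samples, matrix = em)
  truth <- data.frame(gene_id = genes, is_de = seq_len(n_genes) %in% de_idx,
                      direction = ifelse(seq_len(n_genes) %in% de_idx,
                                         ifelse(dir_up, "up", "down"), "ns"),
                      log2fc = log2fc, stringsAsFactors = FALSE)
  list(matrix = em, design = design, truth = truth)
}

#' Simulate a gene-set collection with optional planted sets
#'
#' Random sets are drawn without replacement from the universe, with sizes
#' uniform over `set_size_range`; planted sets are included verbatim (their
#' members must lie in the universe). The result round-trips through
#' [write_gmt()] / [read_gmt()].
#'
#' @param n_sets number of random sets.
#' @param set_size_range length-2 integer range of random set sizes
#'   (default c(15, 50)).
#' @param universe gene ids to draw from.
#' @param planted named list of gene-id vectors included as-is.
#' @param seed RNG seed.
#' @return a `GeneSetCollection`.
#' @export
simulate_genesets <- function(n_sets = 100L, set_size_range = c(15L, 50L),
                              universe, planted = list(), seed = 1L) {
  stopifnot(length(universe) >= max(set_size_range))
  if (length(planted) > 0L) {
    outside <- setdiff(unlist(planted), universe)
    if (length(outside) > 0L) {
      stop("planted genes outside the universe: ",
           paste(utils::head(outside, 5L), collapse = ", "))
    }
  }
  set.seed(seed)
  sizes <- sample(seq(set_size_range[1L], set_size_range[2L]), n_sets,
                  replace = TRUE)
  sets <- lapply(seq_len(n_sets), function(i) sample(universe, sizes[i]))
  names(sets) <- sprintf("random_set_%03d", seq_len(n_sets))
  sets <- c(planted, sets)
  gene_set_collection(sets, category = "simulated")
}

#' Simulate promoter sequences with a planted motif
#'
#' Promoters are i.i.d. uniform A/C/G/T of the given length; each planted
#' gene's promoter receives one exact occurrence of the consensus at a
#' random offset, on a random strand.
#'
#' @param n number of promoters.
#' @param length promoter length, conventionally 300 or 600 nt.
#' @param planted_motif consensus sequence to plant (or `NULL` for none).
#' @param planted_ids gene ids receiving an occurrence (subset of the
#'   generated ids `prom0001`...).
#' @param seed RNG seed.
#' @return named character vector of sequences.
#' @export
simulate_promoters <- function(n = 100L, length = 300L, planted_motif = NULL,
                               planted_ids = character(0), seed = 1L) {
  if (!is.null(planted_motif) && nchar(planted_motif) >= length) {
    stop("consensus must be shorter than the promoter")
  }
  set.seed(seed)
  ids <- sprintf("prom%04d", seq_len(n))
  bad <- setdiff(planted_ids, ids)
  if (length(bad) > 0L) stop("unknown planted ids: ", paste(bad, collapse = ", "))
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
  }, character(1))
  names(seqs) <- ids
  if (!is.null(planted_motif) && length(planted_ids) > 0L) {
    L <- nchar(planted_motif)
    rc <- .revcomp_string(planted_motif)
    for (id in planted_ids) {
      insert <- if (stats::runif(1) < 0.5) planted_motif else rc
      off <- sample.int(length - L + 1L, 1L)
      substr(seqs[[id]], off, off + L - 1L) <- insert
    }
  }
  seqs
}

.revcomp_string <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", toupper(s)), "")[[1]]), collapse = "")
}

#' Write promoter sequences as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output FASTA path.
#' @export
write_promoters_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), filepath = path)
  invisible(path)
}

#' Read promoter sequences from FASTA
#'
#' @param path FASTA file; record ids are taken as gene ids (first
#'   whitespace-separated token of the header).
#' @return named character vector of sequences.
#' @export
read_promoters_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  names(ss) <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1L)
  stats::setNames(as.character(ss), names(ss))
}

#' Simulate a mock identifier-mapping table
#'
#' Builds a table in which each species has its own id space
#' (`<species>_gene<k>` mapping to `<SPECIES>G<k>`); with
#' `overlap_fraction > 0` a fraction of every other species' source ids is
#' also claimed by the first species, so the first species strictly
#' dominates matches for queries drawn from its own ids.
#'
#' @param species_list character vector of species names (>= 1).
#' @param ids_per_species ids generated per species (default 100).
#' @param overlap_fraction fraction of foreign ids duplicated into other
#'   species (default 0).
#' @param seed RNG seed.
#' @return an `IDMappingTable` (same class as [load_mapping_table()]).
#' @export
simulate_mapping <- function(species_list, ids_per_species = 100L,
                             overlap_fraction = 0, seed = 1L) {
  stopifnot(length(species_list) >= 1L, overlap_fraction >= 0,
            overlap_fraction <= 1)
  set.seed(seed)
  recs <- list()
  for (sp in species_list) {
    src <- sprintf("%s_gene%04d", sp, seq_len(ids_per_species))
    can <- sprintf("%sG%06d", toupper(sp), seq_len(ids_per_species))
    recs[[sp]] <- data.frame(source_id = src, canonical_id = can,
                             species = sp, id_type = "symbol",
                             stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, recs)
  if (overlap_fraction > 0 && length(species_list) > 1L) {
    extra <- list()
    for (sp in species_list[-1L]) {
      n_extra <- round(overlap_fraction * ids_per_species)
      if (n_extra == 0L) next
      donors <- sample(recs[[species_list[1L]]]$source_id, n_extra)
      extra[[sp]] <- data.frame(source_id = donors,
                                canonical_id = sprintf("%sG%06d", toupper(sp),
                                                       seq_along(donors) + ids_per_species),
                                species = sp, id_type = "symbol",
                                stringsAsFactors = FALSE)
    }
    df <- rbind(df, do.call(rbind, extra))
  }
  df <- unique(df)
  df$key <- normalize_gene_id(df$source_id)
  rownames(df) <- NULL
  class(df) <- c("IDMappingTable", "data.frame")
  df
}

#' Write an identifier-mapping table as TSV
#'
#' @param table an `IDMappingTable`.
#' @param path output path.
#' @export
write_mapping_table <- function(table, path) {
  stopifnot(inherits(table, "IDMappingTable"))
  utils::write.table(table[c("source_id", "canonical_id", "species", "id_type")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
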