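# shared fixture builders; everything is generated in code, nothing on disk

make_em <- function(values, genes = NULL, samples = NULL,
                    scale_kind = "counts") {
  if (is.null(genes)) genes <- rownames(values)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(values)))
  if (is.null(samples)) samples <- colnames(values)
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  expression_matrix(values, scale_kind = scale_kind)
}

write_matrix_file <- function(values, genes, samples, sep = ",",
                              path = tempfile(fileext = ".csv")) {
  header <- paste(c("gene", samples), collapse = sep)
  rows <- vapply(seq_along(genes), function(i) {
    paste(c(genes[i], values[i, ]), collapse = sep)
  }, character(1))
  writeLines(c(header, rows), path)
  path
}

write_design_file <- function(samples, factors,
                              path = tempfile(fileext = ".csv")) {
  df <- data.frame(sample = samples, factors, check.names = FALSE)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  path
}

# two-group design table for an ExpressionMatrix with 2k columns
two_group_design <- function(em, level_a = "trt", level_b = "ctl") {
  n <- ncol(em$values)
  design_table(list(group = rep(c(level_b, level_a), each = n / 2)),
               sample_ids = colnames(em$values), matrix = em)
}

# a small count-format PWM file: exact consensus with strong counts
write_consensus_pwm_file <- function(consensus, name = "planted",
                                     tf = "TF_planted", family = "testfam",
                                     path = tempfile(fileext = ".txt")) {
  bases <- c("A", "C", "G", "T")
  counts <- vapply(strsplit(consensus, "")[[1]], function(b) {
    as.numeric(bases == b) * 100
  }, numeric(4))
  lines <- c(paste0(">", name, "\t", tf, "\t", family),
             vapply(1:4, function(i) {
               paste0(bases[i], ": ", paste(counts[i, ], collapse = " "))
             }, character(1)))
  writeLines(lines, path)
  path
}

# random probability PWM of width L (for decoys / null calibration)
random_pwm <- function(L = 8L, name = "rand") {
  m <- matrix(stats::runif(4 * L) + 0.2, nrow = 4)
  pwm(sweep(m, 2L, colSums(m), "/"), name = name)
}

# exhaustive oracle: tail probability P(overlap >= k) by enumerating every
# possible query of size n from a universe of size N containing a set of size K
hyper_tail_oracle <- function(N, K, n, k) {
  universe <- seq_len(N)
  inset <- seq_len(K)
  draws <- utils::combn(N, n)
  mean(apply(draws, 2, function(q) sum(q %in% inset) >= k))
}
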