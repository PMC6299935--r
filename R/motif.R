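#' Construct a position weight matrix object
#'
#' @param mat 4 x L numeric matrix of per-position base probabilities, rows
#'   A, C, G, T; columns must each sum to 1 (after pseudocount
#'   normalisation) and L must be at least 4.
#' @param name motif identifier.
#' @param tf_name transcription-factor name (defaults to `name`).
#' @param family TF family label.
#' @return an object of class `PWM`.
#' @export
pwm <- function(mat, name, tf_name = name, family = "") {
  if (!is.matrix(mat) || nrow(mat) != 4L) stop("PWM must have 4 rows (A,C,G,T)")
  if (ncol(mat) < 4L) stop("PWM must span at least 4 positions")
  if (any(mat < 0)) stop("negative probability in PWM")
  if (any(abs(colSums(mat) - 1) > 1e-6)) stop("PWM columns must sum to 1")
  rownames(mat) <- c("A", "C", "G", "T")
  structure(list(name = name, tf_name = tf_name, family = family, mat = mat),
            class = "PWM")
}

.counts_to_probs <- function(counts, pseudocount = 0.01) {
  counts <- counts + pseudocount
  sweep(counts, 2L, colSums(counts), "/")
}

#' Read position weight matrices
#'
#' Two plain-text formats are supported and auto-detected:
#' \itemize{
#'   \item MEME minimal: `MOTIF <id> [<alt name>]` followed by a
#'     `letter-probability matrix:` block of L rows with 4 probabilities
#'     (A C G T order).
#'   \item Count blocks: a header line `>name<TAB>tf<TAB>family` followed by
#'     exactly 4 rows labelled `A:`, `C:`, `G:`, `T:` of per-position
#'     counts. Counts are converted to probabilities with a pseudocount of
#'     0.01 per cell.
#' }
#'
#' @param path PWM file.
#' @param pseudocount added to every count cell before normalisation.
#' @return list of [pwm()] objects.
#' @export
read_pwms <- function(path, pseudocount = 0.01) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (any(grepl("^MOTIF\\b", lines))) {
    .read_pwms_meme(lines)
  } else {
    .read_pwms_counts(lines, pseudocount)
  }
}

.read_pwms_meme <- function(lines) {
  starts <- grep("^MOTIF\\b", lines)
  if (length(starts) == 0L) stop("no MOTIF line found")
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    hdr <- strsplit(trimws(lines[starts[i]]), "\\s+")[[1]]
    name <- hdr[2L]
    alt <- if (length(hdr) >= 3L) hdr[3L] else name
    end <- if (i < length(starts)) starts[i + 1L] - 1L else length(lines)
    block <- lines[starts[i]:end]
    lp <- grep("letter-probability matrix", block)
    if (length(lp) == 0L) stop("motif '", name, "': missing letter-probability matrix")
    rows <- list()
    for (ln in block[-seq_len(lp[1L])]) {
      ln <- trimws(ln)
      if (!nzchar(ln)) { if (length(rows) > 0L) break else next }
      vals <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1]]))
      if (any(is.na(vals))) break
      if (length(vals) != 4L) stop("motif '", name, "': expected 4 probabilities per row")
      rows[[length(rows) + 1L]] <- vals
    }
    mat <- t(do.call(rbind, rows))       # positions were rows; PWM wants 4 x L
    mat <- sweep(mat, 2L, colSums(mat), "/")   # renormalise rounded probs
    out[[i]] <- pwm(mat, name = name, tf_name = alt)
  }
  out
}

.read_pwms_counts <- function(lines, pseudocount) {
  starts <- grep("^>", lines)
  if (length(starts) == 0L) stop("no PWM header ('>name') found")
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    hdr <- strsplit(sub("^>", "", lines[starts[i]]), "\t", fixed = TRUE)[[1]]
    name <- trimws(hdr[1L])
    tf <- if (length(hdr) >= 2L) trimws(hdr[2L]) else name
    fam <- if (length(hdr) >= 3L) trimws(hdr[3L]) else ""
    end <- if (i < length(starts)) starts[i + 1L] - 1L else length(lines)
    block <- lines[(starts[i] + 1L):end]
    block <- block[nzchar(trimws(block))]
    if (length(block) != 4L) {
      stop("PWM '", name, "': expected 4 base rows, found ", length(block))
    }
    base <- toupper(sub("^([A-Za-z]).*", "\\1", trimws(block)))
    if (!identical(sort(base), c("A", "C", "G", "T"))) {
      stop("PWM '", name, "': rows must be labelled A, C, G, T")
    }
    counts <- t(vapply(block, function(ln) {
      vals <- suppressWarnings(as.numeric(
        strsplit(trimws(sub("^[A-Za-z][:|]?\\s*", "", trimws(ln))), "\\s+")[[1]]))
      if (any(is.na(vals))) stop("PWM '", name, "': non-numeric count")
      vals
    }, numeric(length(strsplit(trimws(sub("^[A-Za-z][:|]?\\s*", "", trimws(block[1L]))),
                               "\\s+")[[1]]))))
    rownames(counts) <- base
    counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
    if (any(colSums(counts) == 0)) stop("PWM '", name, "': zero column sum")
    out[[i]] <- pwm(.counts_to_probs(counts, pseudocount), name = name,
                    tf_name = tf, family = fam)
  }
  out
}

.encode_seq <- function(seq) {
  # A=1 C=2 G=3 T=4, anything else (N) = 5
  idx <- match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T"))
  idx[is.na(idx)] <- 5L
  idx
}

.revcomp_idx <- function(idx) {
  # complement under the 1..5 encoding (A<->T, C<->G, N->N), then reverse
  rev(c(4L, 3L, 2L, 1L, 5L)[idx])
}

.best_score <- function(idx, w5) {
  # w5: 5 x L log-odds matrix, 5th row zero (N contributes nothing)
  L <- ncol(w5)
  n_off <- length(idx) - L + 1L
  if (n_off < 1L) return(NA_real_)
  s <- numeric(n_off)
  for (j in seq_len(L)) {
    s <- s + w5[idx[j:(j + n_off - 1L)], j]
  }
  max(s)
}

#' Best PWM log-odds score per promoter
#'
#' Rather than calling binding sites with an arbitrary cutoff, every
#' promoter is summarised by the best log2-odds score each motif achieves
#' over all offsets on both strands:
#' score(placement) = sum over positions of log2(p_base / q_base), with an
#' `N` contributing 0 at its position. The background q defaults to the
#' 0-order base composition pooled over all supplied promoters.
#'
#' @param promoters named character vector of A/C/G/T/N sequences (gene ids
#'   as names), or a `Biostrings::DNAStringSet`.
#' @param pwms list of [pwm()] objects.
#' @param background length-4 base frequencies (A,C,G,T) summing to 1, or
#'   `NULL` for the pooled promoter composition.
#' @return a `MotifScoreMatrix`: promoters x motifs numeric matrix of best
#'   scores (`NA` where the promoter is shorter than the motif), with motif
#'   metadata in attribute `motif_info` and `promoter_length` recording the
#'   per-promoter lengths.
#' @export
scan_best_scores <- function(promoters, pwms, background = NULL) {
  if (inherits(promoters, "DNAStringSet")) {
    promoters <- stats::setNames(as.character(promoters), names(promoters))
  }
  if (is.null(names(promoters)) || anyDuplicated(names(promoters))) {
    stop("promoters must carry unique gene ids as names")
  }
  if (length(pwms) == 0L) stop("no PWMs supplied")
  enc <- lapply(promoters, .encode_seq)
  if (is.null(background)) {
    pooled <- tabulate(unlist(enc), nbins = 5L)[1:4]
    if (sum(pooled) == 0L) {
      background <- rep(0.25, 4)
    } else {
      background <- pooled / sum(pooled)
    }
  }
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-6) {
    stop("'background' must be 4 frequencies summing to 1")
  }
  background <- pmax(background, 1e-9)
  enc_rc <- lapply(enc, .revcomp_idx)
  scores <- matrix(NA_real_, nrow = length(promoters), ncol = length(pwms),
                   dimnames = list(names(promoters),
                                   vapply(pwms, `[[`, character(1), "name")))
  for (j in seq_along(pwms)) {
    w <- log2(pmax(pwms[[j]]$mat, 1e-12) / background)
    w5 <- rbind(w, 0)
    for (i in seq_along(enc)) {
      fwd <- .best_score(enc[[i]], w5)
      rcs <- .best_score(enc_rc[[i]], w5)
      scores[i, j] <- if (is.na(fwd)) NA_real_ else max(fwd, rcs)
    }
  }
  structure(scores,
            motif_info = data.frame(
              motif = colnames(scores),
              tf = vapply(pwms, `[[`, character(1), "tf_name"),
              family = vapply(pwms, `[[`, character(1), "family"),
              stringsAsFactors = FALSE),
            promoter_length = lengths(enc),
            class = c("MotifScoreMatrix", "matrix", "array"))
}

#' Motif enrichment by best-score t-test
#'
#' For each motif, the best promoter scores of a gene list are compared
#' with the scores of all remaining promoters by Welch's t-test; the
#' default alternative is one-sided (`greater`): enrichment means the
#' list's promoters score higher. P-values are BH-corrected across motifs
#' and rows sorted by FDR.
#'
#' @param scores a `MotifScoreMatrix` from [scan_best_scores()].
#' @param query gene ids of the promoter group of interest (>= 3 with
#'   scores; the complement must also have >= 3).
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return data.frame `motif`, `tf`, `family`, `t_statistic`, `p_value`,
#'   `fdr`, sorted by FDR ascending.
#' @export
motif_ttest_enrich <- function(scores, query, alternative = c("greater", "two.sided")) {
  stopifnot(inherits(scores, "MotifScoreMatrix"))
  alternative <- match.arg(alternative)
  in_query <- rownames(scores) %in% query
  info <- attr(scores, "motif_info")
  rows <- lapply(seq_len(ncol(scores)), function(j) {
    a <- scores[in_query, j]
    b <- scores[!in_query, j]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 3L || length(b) < 3L) {
      stop("motif '", colnames(scores)[j],
           "': fewer than 3 scored promoters in the list or its complement")
    }
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      tt <- list(statistic = 0,
                 p.value = if (mean(a) == mean(b)) {
                   if (alternative == "greater") 0.5 else 1
                 } else if (alternative == "two.sided" || mean(a) > mean(b)) 0 else 1)
    } else {
      tt <- stats::t.test(a, b, alternative = alternative)
    }
    data.frame(motif = info$motif[j], tf = info$tf[j], family = info$family[j],
               t_statistic = as.numeric(tt$statistic), p_value = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$fdr, out$p_value, out$motif), ]
  rownames(out) <- NULL
  out
}
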