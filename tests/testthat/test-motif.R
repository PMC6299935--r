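test_that("count-matrix PWMs normalise with the 0.01 pseudocount", {
  path <- write_consensus_pwm_file("ACGT", name = "m1", tf = "TF1")
  pw <- read_pwms(path)
  expect_length(pw, 1L)
  mat <- pw[[1]]$mat
  # column (100, 0, 0, 0) -> (100.01, .01, .01, .01) / 100.04
  expect_equal(unname(mat["A", 1]), 100.01 / 100.04, tolerance = 1e-12)
  expect_equal(unname(mat["C", 1]), 0.01 / 100.04, tolerance = 1e-12)
  expect_equal(unname(colSums(mat)), rep(1, 4), tolerance = 1e-12)
  expect_equal(pw[[1]]$tf_name, "TF1")

  # uniform counts give uniform probabilities
  uni <- tempfile()
  writeLines(c(">u\tU\tfam", "A: 5 5 5 5", "C: 5 5 5 5", "G: 5 5 5 5",
               "T: 5 5 5 5"), uni)
  expect_equal(unname(read_pwms(uni)[[1]]$mat), matrix(0.25, 4, 4))

  # 3-row matrix rejected
  bad <- tempfile()
  writeLines(c(">b\tB", "A: 1 1 1 1", "C: 1 1 1 1", "G: 1 1 1 1"), bad)
  expect_error(read_pwms(bad), "4 base rows")
})

test_that("MEME-minimal PWMs parse with motif and alternate names", {
  path <- tempfile()
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "MOTIF MA0001.1 TFX",
               "letter-probability matrix: alength= 4 w= 4 nsites= 20",
               " 0.970 0.010 0.010 0.010",
               " 0.010 0.970 0.010 0.010",
               " 0.010 0.010 0.970 0.010",
               " 0.010 0.010 0.010 0.970"), path)
  pw <- read_pwms(path)
  expect_equal(pw[[1]]$name, "MA0001.1")
  expect_equal(pw[[1]]$tf_name, "TFX")
  expect_equal(ncol(pw[[1]]$mat), 4L)
  expect_equal(unname(pw[[1]]$mat["A", 1]), 0.97, tolerance = 1e-6)
})

test_that("best score has the closed form for an exact consensus under uniform background", {
  # probability-1 PWM on ACGT, uniform background: each matched position
  # contributes log2(1/0.25) = 2 bits -> best score 8 on a hit
  exact <- pwm(diag(4)[, c(1, 2, 3, 4)], name = "exact")
  sc <- scan_best_scores(c(hit = "GGACGTGG", miss = "CCCCCCCC"),
                         list(exact), background = rep(0.25, 4))
  expect_equal(unname(sc["hit", "exact"]), 8, tolerance = 1e-9)
  expect_lt(sc["miss", "exact"], 0)

  # reverse-complement strand is found too
  sc_rc <- scan_best_scores(c(rc = "GGACGTCC"), list(exact),
                            background = rep(0.25, 4))
  expect_equal(unname(sc_rc["rc", "exact"]), 8, tolerance = 1e-9)

  # all-N promoter scores 0; promoter shorter than the motif is missing
  sc_n <- scan_best_scores(c(n = "NNNNNNNN", short = "AC"), list(exact),
                           background = rep(0.25, 4))
  expect_equal(unname(sc_n["n", "exact"]), 0)
  expect_true(is.na(sc_n["short", "exact"]))
})

test_that("best score is invariant under reverse-complementing promoters", {
  set.seed(61)
  proms <- simulate_promoters(8, 60, seed = 62)
  pwms <- lapply(1:3, function(i) random_pwm(7, sprintf("m%d", i)))
  fwd <- scan_best_scores(proms, pwms, background = rep(0.25, 4))
  rc <- vapply(proms, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1))
  bwd <- scan_best_scores(rc, pwms, background = rep(0.25, 4))
  expect_equal(unname(fwd), unname(bwd), tolerance = 1e-10)
})

test_that("appending flanking sequence never lowers the best score", {
  set.seed(63)
  proms <- simulate_promoters(6, 50, seed = 64)
  pwms <- list(random_pwm(6, "m"))
  base <- scan_best_scores(proms, pwms, background = rep(0.25, 4))
  flanked <- paste0(proms, vapply(seq_along(proms), function(i) {
    paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = "")
  }, character(1)))
  names(flanked) <- names(proms)
  more <- scan_best_scores(flanked, pwms, background = rep(0.25, 4))
  expect_true(all(more >= base - 1e-10))
})

test_that("planted motif occurrences are detected by the best-score t-test", {
  set.seed(65)
  consensus <- "TGACGTCA"
  query_ids <- sprintf("prom%04d", 1:50)
  proms <- simulate_promoters(100, 300, planted_motif = consensus,
                              planted_ids = query_ids, seed = 66)
  pwms <- c(list(read_pwms(write_consensus_pwm_file(consensus))[[1]]),
            lapply(1:20, function(i) random_pwm(8, sprintf("decoy%02d", i))))
  sc <- scan_best_scores(proms, pwms)
  tab <- motif_ttest_enrich(sc, query_ids)
  expect_equal(tab$motif[1], "planted")
  expect_lt(tab$fdr[1], 0.05)
  expect_equal(tab$tf[1], "TF_planted")
  expect_equal(tab$family[1], "testfam")
})

test_that("identical score distributions give t = 0 and one-sided p >= 0.5", {
  scores <- matrix(rep(c(1, 2, 3, 4), 3), nrow = 12, ncol = 1,
                   dimnames = list(paste0("p", 1:12), "m"))
  obj <- structure(scores,
                   motif_info = data.frame(motif = "m", tf = "T", family = "f"),
                   promoter_length = rep(300L, 12),
                   class = c("MotifScoreMatrix", "matrix", "array"))
  tab <- motif_ttest_enrich(obj, paste0("p", 1:4))   # same values both groups
  expect_equal(tab$t_statistic, 0, tolerance = 1e-12)
  expect_gte(tab$p_value, 0.5)

  expect_error(motif_ttest_enrich(obj, paste0("p", 1:2)), "fewer than 3")
})
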