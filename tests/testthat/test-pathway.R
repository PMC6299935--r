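test_that("PAGE Z matches the closed form on the 5-value worked case", {
  # scores {1..5}, set = genes valued {4,5}: mu = 3, sigma = sd(1:5),
  # Z = (4.5 - 3) * sqrt(2) / sqrt(2.5) ~= 1.342, two-tailed p ~= 0.180
  fc5 <- setNames(as.numeric(1:5), paste0("g", 1:5))
  coll <- gene_set_collection(list(S = c("g4", "g5")))
  z_expect <- (mean(c(4, 5)) - mean(1:5)) * sqrt(2) / sd(1:5)
  res <- page_scores(fc5, coll, size_min = 1, size_max = 10)
  expect_equal(res$z, z_expect, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pnorm(-abs(z_expect)), tolerance = 1e-12)
})

test_that("PAGE handles the worked example, identity set and permutation oracle", {
  fc <- setNames(as.numeric(1:5), paste0("g", 1:5))
  fc <- c(fc, setNames(rep(3, 5), paste0("pad", 1:5)))  # pad to >= 10 genes
  # identity case: the set of all genes has Z = 0, p = 1
  coll_all <- gene_set_collection(list(all = names(fc)))
  res_all <- page_scores(fc, coll_all, size_min = 1, size_max = 100)
  expect_equal(res_all$z, 0, tolerance = 1e-12)
  expect_equal(res_all$p_value, 1)

  # permutation oracle: Z of random same-size sets is ~ N(0,1), so the
  # analytic two-tailed p at the observed Z matches the permutation tail
  set.seed(51)
  scores <- setNames(rnorm(2000), paste0("r", 1:2000))
  m <- 20
  perm_z <- replicate(10000, {
    members <- sample(names(scores), m)
    (mean(scores[members]) - mean(scores)) * sqrt(m) / sd(scores)
  })
  expect_lt(abs(mean(abs(perm_z) > 1.341641) - 2 * pnorm(-1.341641)), 0.02)
  expect_lt(abs(unname(quantile(abs(perm_z), 0.95)) - qnorm(0.975)), 0.08)
})

test_that("abs-mode scores the magnitudes of fold-changes", {
  set.seed(52)
  fc <- setNames(rnorm(100), paste0("g", 1:100))
  both_dir <- names(fc)[order(-abs(fc))][1:15]   # largest |fc|, mixed signs
  coll <- gene_set_collection(list(S = both_dir))
  plain <- page_scores(fc, coll)
  absed <- page_scores(fc, coll, abs_mode = TRUE)
  expect_gt(absed$z, plain$z)
  expect_lt(absed$p_value, 0.001)
})

test_that("per-sample activity is zero for the all-genes set and antisymmetric for 2 samples", {
  set.seed(53)
  vals <- matrix(rnorm(60 * 2, 8), nrow = 60)
  em <- make_em(vals, scale_kind = "transformed")
  coll <- gene_set_collection(list(all = gene_ids(em), sub = gene_ids(em)[1:20]))
  act <- pgsea_sample_scores(em, coll, size_min = 1, size_max = 100)
  expect_equal(unname(act$z["all", ]), c(0, 0), tolerance = 1e-10)
  # after row-centring, two samples are mirror images
  expect_equal(act$z["sub", 1], -act$z["sub", 2], tolerance = 1e-10)
})

test_that("per-sample activity is invariant to a constant added to a sample", {
  set.seed(54)
  em <- make_em(matrix(rnorm(80 * 4, 8), nrow = 80), scale_kind = "transformed")
  coll <- gene_set_collection(list(S = gene_ids(em)[1:25]))
  a1 <- pgsea_sample_scores(em, coll, size_min = 1)
  shifted <- em$values; shifted[, 2] <- shifted[, 2] + 5
  a2 <- pgsea_sample_scores(make_em(shifted, scale_kind = "transformed"),
                            coll, size_min = 1)
  expect_equal(a1$z, a2$z, tolerance = 1e-10)
})

test_that("a planted differential pathway gets opposite-sign Z and tops the ANOVA ranking", {
  set.seed(55)
  vals <- matrix(rnorm(200 * 10, 8, 1), nrow = 200)
  vals[1:30, 6:10] <- vals[1:30, 6:10] + 2       # set genes up in group 2
  em <- make_em(vals, scale_kind = "transformed")
  design <- two_group_design(em)
  coll <- simulate_genesets(20, c(15, 30), universe = gene_ids(em),
                            planted = list(planted = gene_ids(em)[1:30]),
                            seed = 56)
  act <- pgsea_sample_scores(em, coll)
  expect_true(all(act$z["planted", 6:10] > 0))
  expect_true(all(act$z["planted", 1:5] < 0))

  ranked <- anova_rank_pathways(act, design, "group", fdr_cut = 0.05)
  expect_equal(ranked$table$set[1], "planted")
  expect_lt(ranked$table$fdr[1], 0.05)
  # ordering is deterministic: spread descending, then name
  expect_equal(order(-ranked$table$spread, ranked$table$set),
               seq_len(nrow(ranked$table)))
})

test_that("constant-activity sets carry no contrast and are filtered", {
  z <- rbind(flat = rep(0.3, 6), real = c(1, 1.2, 0.9, -1, -1.1, -0.8))
  colnames(z) <- paste0("s", 1:6)
  act <- structure(list(z = z, set_sizes = c(flat = 20L, real = 20L)),
                   class = "PathwayActivityMatrix")
  em <- make_em(matrix(rnorm(12, 5), nrow = 2), samples = colnames(z),
                scale_kind = "transformed")
  design <- two_group_design(em)
  ranked <- anova_rank_pathways(act, design, "group", fdr_cut = 0.05)
  expect_equal(ranked$all_sets$anova_p[ranked$all_sets$set == "flat"], 1)
  expect_false("flat" %in% ranked$table$set)
})

test_that("ANOVA oracle: vectorised F matches stats::aov per set", {
  set.seed(57)
  z <- matrix(rnorm(5 * 9), nrow = 5,
              dimnames = list(paste0("set", 1:5), paste0("s", 1:9)))
  act <- structure(list(z = z, set_sizes = rep(20L, 5)),
                   class = "PathwayActivityMatrix")
  em <- make_em(matrix(rnorm(18, 5), nrow = 2), samples = colnames(z),
                scale_kind = "transformed")
  design <- design_table(list(group = rep(c("a", "b", "c"), each = 3)),
                         sample_ids = colnames(z), matrix = em)
  ranked <- anova_rank_pathways(act, design, "group", fdr_cut = 1, top_k = 5)
  for (i in 1:5) {
    ref <- summary(aov(z[i, ] ~ factor(rep(c("a", "b", "c"), each = 3))))[[1]]
    expect_equal(ranked$all_sets$anova_p[i], ref[["Pr(>F)"]][1],
                 tolerance = 1e-10)
  }
})

test_that("PCA-loading pathway analysis finds a planted loading set and skips duplicates", {
  set.seed(58)
  genes <- paste0("g", 1:100)
  loadings <- cbind(PC1 = c(rep(0.3, 20), rnorm(80, 0, 0.02)),
                    PC2 = rnorm(100, 0, 0.02))
  rownames(loadings) <- genes
  pca <- structure(list(scores = matrix(0, 4, 2), loadings = loadings,
                        variance_fraction = c(0.7, 0.3)),
                   class = "PCAResult")
  coll <- simulate_genesets(10, c(15, 25), universe = genes,
                            planted = list(planted = genes[1:20]), seed = 59)
  res <- pca_loading_pathways(pca, coll, n_components = 2, per_pc = 5)
  pc1 <- res[res$component == "PC1", ]
  expect_equal(pc1$set[1], "planted")
  expect_lt(pc1$fdr[1], 0.01)
  # a set reported for PC1 never reappears for PC2
  expect_equal(intersect(res$set[res$component == "PC1"],
                         res$set[res$component == "PC2"]), character(0))
  # labels carry FDR then component
  expect_match(res$label[1], "PC1$")
})

test_that("flat loadings yield no significant pathway", {
  genes <- paste0("g", 1:50)
  loadings <- cbind(PC1 = rep(0.1, 50))
  rownames(loadings) <- genes
  pca <- structure(list(scores = matrix(0, 4, 1), loadings = loadings,
                        variance_fraction = 1),
                   class = "PCAResult")
  coll <- gene_set_collection(list(S = genes[1:20]))
  res <- pca_loading_pathways(pca, coll, n_components = 1)
  expect_equal(res$t_statistic, 0)
  expect_equal(res$p_value, 1)
})
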