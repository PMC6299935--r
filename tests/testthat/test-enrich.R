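test_that("GMT files load with deduplication and malformed-line errors", {
  path <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3\tg2",   # duplicate member stored once
               "setB\tother\tg4\tg5"), path)
  coll <- read_gmt(path)
  expect_equal(length(coll$sets), 2L)
  expect_equal(coll$sets$setA, c("g1", "g2", "g3"))

  bad <- tempfile(); writeLines(c("setA\tdesc\tg1", "lonely"), bad)
  expect_error(read_gmt(bad), "malformed GMT line 2")

  empty_set <- tempfile(); writeLines(c("setA\tdesc\tg1", "setB\tdesc"), empty_set)
  expect_warning(coll2 <- read_gmt(empty_set), "empty set")
  expect_equal(names(coll2$sets), "setA")

  # round-trip through write_gmt
  out <- tempfile(fileext = ".gmt")
  write_gmt(coll, out)
  expect_equal(read_gmt(out)$sets, coll$sets)
})

test_that("hypergeometric p equals the exact tail sum on the worked case", {
  # N = 20, K = 5, n = 6, k = 3: exact tail 5090 / 38760
  universe <- paste0("g", 1:20)
  coll <- gene_set_collection(list(S = universe[1:5]))
  query <- c(universe[1:3], universe[6:8])       # overlap 3
  tab <- hypergeometric_enrich(query, coll, background = universe,
                               size_min = 1, size_max = 100)
  expect_equal(tab$p_value, 5090 / 38760, tolerance = 1e-12)
  expect_equal(tab$k, 3L)
  expect_equal(tab$K, 5L)

  # zero overlap: p = P(X >= 0) = 1
  none <- hypergeometric_enrich(universe[6:10], coll, background = universe,
                                size_min = 1, size_max = 100)
  expect_equal(none$p_value, 1)
})

test_that("hypergeometric p matches exhaustive enumeration on small universes", {
  for (case in list(c(8, 3, 4), c(10, 4, 5), c(12, 5, 6), c(11, 6, 3))) {
    N <- case[1]; K <- case[2]; n <- case[3]
    universe <- paste0("u", seq_len(N))
    coll <- gene_set_collection(list(S = universe[seq_len(K)]))
    for (k in 0:min(K, n)) {
      query <- c(universe[seq_len(k)], universe[K + seq_len(n - k)])
      tab <- hypergeometric_enrich(query, coll, background = universe,
                                   size_min = 1, size_max = N)
      expect_equal(tab$p_value, hyper_tail_oracle(N, K, n, k),
                   tolerance = 1e-12)
    }
  }
})

test_that("a query drawn from a set gives that set the best p among same-size sets", {
  universe <- paste0("g", 1:10)
  sets <- list(target = universe[1:4], other1 = universe[3:6],
               other2 = universe[7:10])
  coll <- gene_set_collection(sets)
  tab <- hypergeometric_enrich(universe[1:4], coll, background = universe,
                               size_min = 1, size_max = 10)
  expect_equal(tab$set[1], "target")
  # brute force: no size-4 query can give a smaller p than the set itself
  best <- min(apply(utils::combn(10, 4), 2, function(q) {
    k <- sum(universe[q] %in% sets$target)
    phyper(k - 1, 4, 6, 4, lower.tail = FALSE)
  }))
  expect_equal(tab$p_value[tab$set == "target"], best, tolerance = 1e-12)
})

test_that("planted enrichment ranks the seeded set first", {
  set.seed(41)
  universe <- paste0("g", sprintf("%03d", 1:300))
  coll <- simulate_genesets(30, c(15, 30), universe = universe,
                            planted = list(planted = universe[1:20]), seed = 42)
  # query: half from the planted set, half random background
  query <- c(universe[1:10], sample(universe[150:300], 10))
  tab <- hypergeometric_enrich(query, coll, background = universe)
  expect_equal(tab$set[1], "planted")
})

test_that("BH rejection rate under a complete null matches the FDR level", {
  # under independence, BH at level q rejects anything with probability ~ q
  set.seed(43)
  any_rejection <- replicate(1000, {
    any(p.adjust(runif(400), "BH") < 0.05)
  })
  expect_lt(abs(mean(any_rejection) - 0.05), 0.02)
})

test_that("term overlap distance implements the overlap-coefficient complement", {
  expect_equal(term_overlap_distance(c("a", "b"), c("a", "b")), 0)
  expect_equal(term_overlap_distance(c("a", "b"), c("c", "d")), 1)
  # |A∩B| = 2, |A| = 4, |B| = 6 -> 1 - 2/4
  A <- paste0("g", 1:4); B <- paste0("g", c(1, 2, 5, 6, 7, 8))
  expect_equal(term_overlap_distance(A, B), 0.5)
  expect_equal(term_overlap_distance(A, B, method = "jaccard"), 1 - 2 / 8)
  expect_error(term_overlap_distance(character(0), "a"), "empty")
})

test_that("term summary builds tree and thresholded network", {
  tab <- structure(
    data.frame(set = c("t1", "t2", "t3"), k = c(3L, 3L, 2L), K = 10L,
               n = 5L, N = 100L, p_value = c(1e-4, 2e-4, 0.01),
               fdr = c(3e-4, 3e-4, 0.01),
               overlap_genes = c("a,b,c", "a,b,c", "x,y")),
    class = c("EnrichmentTable", "data.frame"))
  res <- build_term_summary(tab, edge_threshold = 0.5)
  # identical member lists merge at height 0 and are connected
  expect_equal(res$tree$height[1], 0, tolerance = 1e-12)
  expect_equal(nrow(res$edges), 1L)
  expect_setequal(unlist(res$edges[1, c("from", "to")]), c("t1", "t2"))
  expect_equal(res$nodes$neg_log10_fdr[1], -log10(3e-4), tolerance = 1e-12)
  expect_match(res$newick, "t3")

  # disjoint pair below threshold: no edge
  tab2 <- tab[c(1, 3), ]
  class(tab2) <- class(tab)
  res2 <- build_term_summary(tab2, edge_threshold = 0.5)
  expect_equal(nrow(res2$edges), 0L)

  # single term: singleton node, no tree
  tab1 <- tab[1, ]; class(tab1) <- class(tab)
  res1 <- build_term_summary(tab1)
  expect_null(res1$tree)
  expect_equal(nrow(res1$nodes), 1L)
})
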