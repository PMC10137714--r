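test_that("correlate matches cor.test and flags constant input", {
  set.seed(2)
  x <- rnorm(10); y <- rnorm(10)
  cc <- correlate(x, y)
  ref <- cor.test(x, y)
  expect_equal(cc$r, unname(ref$estimate))
  expect_equal(cc$p, ref$p.value)
  expect_false(cc$degenerate)
  flat <- correlate(rep(1, 10), y)
  expect_true(flat$degenerate)
  expect_true(is.na(flat$r))
  expect_error(correlate(x, y[1:5]), "length mismatch")
  expect_error(correlate(x[1:2], y[1:2]), "at least 3")
})

test_that("edges require opposite DE direction and negative co-expression", {
  de_reg <- data.frame(feature_id = c("r1", "r2", "r3"),
                       direction = c("up_in_B", "up_in_B", "ns"))
  de_tgt <- data.frame(feature_id = c("g1", "g2", "g3"),
                       direction = c("up_in_A", "up_in_B", "up_in_A"))
  hits <- data.frame(regulator_id = c("r1", "r2", "r3"),
                     gene_id = c("g1", "g2", "g3"),
                     mfe = c(-30, -30, -30))
  samples <- sprintf("s%d", 1:6)
  reg_expr <- rbind(r1 = c(1, 2, 3, 10, 11, 12),
                    r2 = c(1, 2, 3, 10, 11, 12),
                    r3 = c(5, 5, 6, 5, 6, 5))
  tgt_expr <- rbind(g1 = c(12, 11, 10, 3, 2, 1),   # anti-correlated with r1
                    g2 = c(1, 2, 3, 10, 11, 12),   # same direction as r2
                    g3 = c(12, 11, 10, 3, 2, 1))
  colnames(reg_expr) <- colnames(tgt_expr) <- samples
  edges <- build_network(de_reg, de_tgt, hits, reg_expr, tgt_expr)
  # r3 is ns: its hit never becomes a candidate edge
  expect_setequal(edges$regulator_id, c("r1", "r2"))
  expect_true(edges$retained[edges$regulator_id == "r1"])   # opposite + anti-corr
  expect_false(edges$retained[edges$regulator_id == "r2"])  # same direction
  expect_lt(edges$pearson_r[edges$regulator_id == "r1"], 0)
})

test_that("an optional correlation p-value cut removes weakly supported edges", {
  de_reg <- data.frame(feature_id = "r1", direction = "up_in_B")
  de_tgt <- data.frame(feature_id = "g1", direction = "up_in_A")
  hits <- data.frame(regulator_id = "r1", gene_id = "g1", mfe = -25)
  set.seed(3)
  reg_expr <- matrix(c(1, 2, 3, 10, 11, 12), 1,
                     dimnames = list("r1", sprintf("s%d", 1:6)))
  # weakly negative, noisy target
  tgt_expr <- matrix(c(5, 9, 4, 6, 3, 5), 1,
                     dimnames = list("g1", sprintf("s%d", 1:6)))
  open <- build_network(de_reg, de_tgt, hits, reg_expr, tgt_expr)
  strict <- build_network(de_reg, de_tgt, hits, reg_expr, tgt_expr,
                          corr_p_max = 0.01)
  expect_true(open$retained)
  expect_false(strict$retained)
})

test_that("hub degrees count retained edges only, ties broken by id", {
  edges <- data.frame(
    regulator_id = c("r1", "r1", "r2", "r2"),
    target_gene_id = c("g1", "g2", "g3", "g4"),
    mfe = -30, pearson_r = -0.9, corr_p = 0.01,
    retained = c(TRUE, TRUE, TRUE, FALSE)
  )
  hubs <- hub_nodes(edges, k = 3L)
  expect_equal(hubs$node[1], "r1")
  expect_equal(hubs$degree[1], 2L)
  expect_equal(hubs$node[2:3], c("g1", "g2"))  # degree-1 ties, id order
  expect_equal(nrow(hub_nodes(edges[edges$retained == FALSE, ], 3L)), 0L)
})

test_that("hypergeometric enrichment matches the closed-form tail", {
  universe <- sprintf("g%02d", 1:20)
  sets <- list(hit_set = universe[1:5], other = universe[6:15])
  # query is exactly the 5-gene set: p = 1 / choose(20, 5)
  res <- ora_hypergeometric(universe[1:5], universe, sets)
  expect_equal(res$p_value[res$term_id == "hit_set"], 1 / choose(20, 5),
               tolerance = 1e-12)
  # zero overlap: p is the probability of >= 0 successes = 1
  expect_equal(res$p_value[res$term_id == "other"], 1, tolerance = 1e-12)
  # partial overlap against the closed-form sum
  res2 <- ora_hypergeometric(universe[c(1, 2, 6, 7, 8)], universe, sets)
  k <- 2; m <- 5; N <- 20; q <- 5
  closed <- sum(vapply(k:min(m, q), function(i) {
    choose(m, i) * choose(N - m, q - i) / choose(N, q)
  }, 0))
  expect_equal(res2$p_value[res2$term_id == "hit_set"], closed,
               tolerance = 1e-12)
  expect_equal(res$fdr, p.adjust(res$p_value, "BH"))
  expect_error(ora_hypergeometric("absent", universe, sets), "subset")
})

test_that("GMT files round-trip into named gene-set lists", {
  path <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg4"), path)
  sets <- read_gmt(path)
  expect_equal(names(sets), c("setA", "setB"))
  expect_equal(sets$setA, c("g1", "g2", "g3"))
  expect_equal(sets$setB, "g4")
  unlink(path)
})

test_that("the GSEA enrichment score equals the brute-force running sum", {
  set.seed(4)
  genes <- sprintf("g%02d", 1:10)
  scores <- sort(rnorm(10), decreasing = TRUE)
  names(scores) <- genes
  for (set in list(genes[c(1, 2, 3)], genes[c(8, 9, 10)], genes[c(2, 5, 9)])) {
    es_pkg <- tsrnaflow:::gsea_running_es(genes, unname(scores), set)
    es_bf <- brute_gsea_es(genes, unname(scores), set)
    expect_equal(es_pkg, es_bf, tolerance = 1e-12)
  }
  # top-loaded sets score positive, bottom-loaded negative
  expect_gt(tsrnaflow:::gsea_running_es(genes, unname(scores), genes[1:3]), 0)
  expect_lt(tsrnaflow:::gsea_running_es(genes, unname(scores), genes[8:10]), 0)
})

test_that("preranked GSEA separates a loaded set from a random one", {
  set.seed(8)
  scores <- c(sort(rnorm(20, 3), decreasing = TRUE), rnorm(80))
  names(scores) <- sprintf("g%03d", 1:100)
  sets <- list(loaded = names(scores)[1:20],
               random = sample(names(scores), 20))
  res <- gsea_preranked(scores, sets, n_perm = 200, seed = 1)
  expect_gt(res$es[res$term_id == "loaded"], 0)
  expect_lt(res$p_value[res$term_id == "loaded"],
            res$p_value[res$term_id == "random"])
  expect_lt(res$p_value[res$term_id == "loaded"], 0.05)
  # identical calls are deterministic
  res2 <- gsea_preranked(scores, sets, n_perm = 200, seed = 1)
  expect_identical(res, res2)
  expect_warning(gsea_preranked(scores, list(empty = "absent_gene")),
                 "skipped")
})
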