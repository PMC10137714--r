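test_that("RPM columns sum to one million and equalization hits the geometric mean", {
  set.seed(1)
  counts <- matrix(rpois(60, 40), nrow = 10,
                   dimnames = list(sprintf("f%02d", 1:10), sprintf("s%d", 1:6)))
  rpm <- normalize_rpm(counts)
  expect_true(all(abs(colSums(rpm) - 1e6) < 1e-6))
  eq <- equalize_lib_sizes(counts)
  target <- exp(mean(log(colSums(counts))))
  expect_true(all(abs(colSums(eq) - target) < 1e-9))
  # explicit library sizes override column sums
  eq2 <- equalize_lib_sizes(counts, lib_sizes = rep(1000, 6))
  expect_equal(eq2, counts * 1)
  expect_error(normalize_rpm(cbind(counts, 0)), "zero library size")
})

test_that("the zero-dispersion exact test reduces to the exact binomial test", {
  for (case in list(c(30, 10), c(5, 5), c(0, 12), c(100, 55))) {
    sa <- case[1]; sb <- case[2]
    p_pkg <- tsrnaflow:::nb_exact_pvalue_one(sa, sb, na = 3, nb = 3, phi = 0)
    p_ref <- stats::binom.test(sa, sa + sb, p = 0.5)$p.value
    expect_equal(p_pkg, p_ref, tolerance = 1e-12)
  }
  # unequal group sizes shift the null proportion
  p_pkg <- tsrnaflow:::nb_exact_pvalue_one(20, 5, na = 4, nb = 2, phi = 0)
  p_ref <- stats::binom.test(20, 25, p = 4 / 6)$p.value
  expect_equal(p_pkg, p_ref, tolerance = 1e-12)
})

test_that("exact NB p-values sum the conditional pmf over the minimum-likelihood tail", {
  # independent enumeration of the conditional distribution
  cond_p <- function(sa, sb, na, nb, phi) {
    t <- sa + sb
    mu <- t / (na + nb)
    s <- 0:t
    pr <- stats::dnbinom(s, size = na / phi, mu = na * mu) *
      stats::dnbinom(t - s, size = nb / phi, mu = nb * mu)
    pr <- pr / sum(pr)
    sum(pr[pr <= pr[sa + 1] * (1 + 1e-10)])
  }
  for (case in list(c(40, 12), c(8, 8), c(3, 25))) {
    p_pkg <- tsrnaflow:::nb_exact_pvalue_one(case[1], case[2], 3, 3, 0.1)
    expect_equal(p_pkg, cond_p(case[1], case[2], 3, 3, 0.1), tolerance = 1e-9)
  }
  # symmetric design: swapping the groups leaves p unchanged
  expect_equal(tsrnaflow:::nb_exact_pvalue_one(40, 12, 3, 3, 0.1),
               tsrnaflow:::nb_exact_pvalue_one(12, 40, 3, 3, 0.1),
               tolerance = 1e-12)
})

test_that("the common-dispersion estimator recovers the generating dispersion", {
  set.seed(7)
  phi <- 0.1
  mu <- rep(100, 2000)
  counts <- vapply(1:6, function(j) rnbinom(2000, size = 1 / phi, mu = mu), numeric(2000))
  colnames(counts) <- c("A1", "A2", "A3", "B1", "B2", "B3")
  grp <- rep(c("A", "B"), each = 3)
  phi_hat <- estimate_common_dispersion(counts, grp,
                                        lib_sizes = rep(1e6, 6))
  expect_gt(phi_hat, 0.05)
  expect_lt(phi_hat, 0.15)
  # Poisson data floors at zero-ish
  pois <- vapply(1:6, function(j) rpois(2000, 100), numeric(2000))
  colnames(pois) <- colnames(counts)
  expect_lt(estimate_common_dispersion(pois, grp, lib_sizes = rep(1e6, 6)), 0.02)
  expect_error(estimate_common_dispersion(counts[, 1:3], rep("A", 3)),
               "two groups")
  expect_error(estimate_common_dispersion(counts[, c(1, 4)], c("A", "B")),
               "replicates")
})

test_that("planted fold changes among nulls are detected with correct direction", {
  set.seed(42)
  phi <- 0.1
  n_null <- 400
  n_de <- 40
  mu <- rlnorm(n_null + n_de, log(200), 1)
  counts <- matrix(0, n_null + n_de, 6,
                   dimnames = list(sprintf("f%04d", seq_len(n_null + n_de)),
                                   c("A1", "A2", "A3", "B1", "B2", "B3")))
  lfc <- c(rep(0, n_null), rep(2, n_de))
  for (j in 1:6) {
    m <- if (j <= 3) mu else mu * 2^(-lfc)
    counts[, j] <- rnbinom(n_null + n_de, size = 1 / phi, mu = m)
  }
  res <- nb_exact_test(counts, rep(c("A", "B"), each = 3), dispersion = phi,
                       lib_sizes = rep(1e6, 6))
  planted <- res$feature_id %in% rownames(counts)[(n_null + 1):(n_null + n_de)]
  expect_gt(mean(res$significant[planted]), 0.8)
  expect_true(all(res$direction[planted & res$significant] == "up_in_A"))
  expect_lt(mean(res$significant[!planted]), 0.1)
  # fold-change estimates center on the planted effect
  expect_equal(median(res$log2fc[planted]), 2, tolerance = 0.4)
})

test_that("all-zero features are reported as null, not significant", {
  counts <- rbind(f1 = c(5, 6, 4, 20, 30, 25), f2 = rep(0, 6))
  res <- nb_exact_test(counts, rep(c("A", "B"), each = 3), dispersion = 0.1)
  z <- res[res$feature_id == "f2", ]
  expect_equal(z$p_value, 1)
  expect_equal(z$log2fc, 0)
  expect_false(z$significant)
  expect_equal(z$direction, "ns")
})

test_that("FDR is Benjamini-Hochberg and significance uses the raw-p rule", {
  set.seed(9)
  counts <- matrix(rnbinom(600, size = 10, mu = 50), 100, 6,
                   dimnames = list(sprintf("f%03d", 1:100), NULL))
  colnames(counts) <- c("A1", "A2", "A3", "B1", "B2", "B3")
  res <- nb_exact_test(counts, rep(c("A", "B"), each = 3), dispersion = 0.1)
  expect_equal(res$fdr, p.adjust(res$p_value, "BH"))
  expect_equal(res$significant,
               abs(res$log2fc) >= 1 & res$p_value <= 0.05)
})

test_that("count matrices round-trip with their group sidecar", {
  counts <- matrix(1:12, 3, 4,
                   dimnames = list(c("a", "b", "c"), c("A1", "A2", "B1", "B2")))
  path <- tempfile(fileext = ".tsv")
  write_count_matrix(counts, path, group = c("A", "A", "B", "B"))
  back <- read_count_matrix(path)
  expect_equal(back$counts, counts)
  expect_equal(unname(back$group), c("A", "A", "B", "B"))
  unlink(c(path, paste0(path, ".groups.tsv")))
})

test_that("de_summary tallies directions and z-scores significant features", {
  res <- data.frame(
    feature_id = c("a", "b", "c"),
    log2fc = c(2, -2, 0), p_value = c(0.01, 0.01, 0.9),
    fdr = c(0.02, 0.02, 0.9),
    significant = c(TRUE, TRUE, FALSE),
    direction = c("up_in_A", "up_in_B", "ns")
  )
  counts <- matrix(c(40, 4, 10, 38, 5, 11, 4, 40, 9, 5, 41, 10), 3, 4,
                   dimnames = list(c("a", "b", "c"), c("A1", "A2", "B1", "B2")))
  s <- de_summary(res, counts)
  expect_equal(unname(s$tally), c(1, 1))
  expect_equal(rownames(s$zscore), c("a", "b"))
  expect_true(all(abs(rowMeans(s$zscore)) < 1e-12))
})
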