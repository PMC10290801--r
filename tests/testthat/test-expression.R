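test_that("RPKM evaluates its formula and is scale invariant", {
  expect_equal(rpkm(10, 1000, 1e6), 10)
  expect_equal(rpkm(0, 1500, 2e6), 0)
  expect_equal(rpkm(1000, 500, 1e6), 2000)
  expect_error(rpkm(5, 0, 1e6), "length")
  expect_error(rpkm(5, 1000, 0), "library")
  # multiplying counts and library size by k leaves RPKM unchanged
  for (k in c(2, 10, 1000))
    expect_equal(rpkm(17 * k, 1200, 3e6 * k), rpkm(17, 1200, 3e6))
})

test_that("expressed call thresholds at log2 RPKM of 1, boundary inclusive", {
  expect_false(expressed_call(0.5))
  expect_true(expressed_call(1.0))
  expect_true(expressed_call(5.0))
  expect_false(expressed_call(-Inf))  # zero RPKM
  expect_equal(floor_expression(c(1.9, 2.0, 50)), c(0, 2.0, 50))
})

test_that("categories follow the truth table and partition any gene set", {
  expect_equal(categorize(FALSE, FALSE), "Cat1")
  expect_equal(categorize(FALSE, TRUE), "Cat2")
  expect_equal(categorize(TRUE, FALSE), "Cat2")
  expect_equal(categorize(TRUE, TRUE), "Cat3")
  set.seed(5)
  e24 <- sample(c(TRUE, FALSE), 500, replace = TRUE)
  e48 <- sample(c(TRUE, FALSE), 500, replace = TRUE)
  cats <- categorize(e24, e48)
  expect_equal(sum(cats == "Cat1") + sum(cats == "Cat2") + sum(cats == "Cat3"),
               500L)
})

test_that("TMM factors are 1 for identical and depth-scaled columns", {
  set.seed(9)
  a <- rnbinom(3000, mu = exp(rnorm(3000, log(80), 1)), size = 10)
  expect_equal(tmm_factors(cbind(a, a)), c(1, 1))
  # doubling depth changes no composition: factors stay within 1% of 1
  expect_equal(tmm_factors(cbind(a, 2 * a)), c(1, 1), tolerance = 0.01)
})

test_that("TMM factors have geometric mean 1 and ignore gene order", {
  set.seed(10)
  m <- matrix(rnbinom(4000 * 4, mu = exp(rnorm(16000, log(60), 1)), size = 8),
              ncol = 4)
  f <- tmm_factors(m)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
  perm <- sample(nrow(m))
  expect_equal(tmm_factors(m[perm, ]), f)
  expect_error(tmm_factors(cbind(m[, 1], 0 * m[, 1])), "all-zero")
})

test_that("TMM agrees with the edgeR reference implementation", {
  skip_if_not_installed("edgeR")
  set.seed(12)
  m <- matrix(rnbinom(5000 * 4, mu = exp(rnorm(20000, log(100), 1.2)), size = 5),
              ncol = 4)
  # perturb one sample's composition
  m[1:200, 2] <- m[1:200, 2] * 6L
  expect_equal(tmm_factors(m), as.numeric(edgeR::calcNormFactors(m)),
               tolerance = 0.02)
})

test_that("differential test handles identical groups, rules and degeneracy", {
  lib <- rep(1e6, 3)
  same <- differential(c(100, 110, 95), c(100, 110, 95), lib, lib)
  expect_equal(same$log2fc, 0)
  expect_false(same$significant)

  # the significance and fold-change rules are independent
  d <- differential(c(100, 101, 99), c(172, 175, 170), lib, lib)
  expect_true(d$p_value < 0.05 && d$significant)
  expect_true(abs(d$log2fc) < 1 && !d$strong)

  # exact equality with zero variance: p = 1
  flat <- differential(c(50, 50, 50), c(50, 50, 50), lib, lib)
  expect_equal(flat$p_value, 1)

  # single replicates: no p-value, never significant
  single <- differential(10, 80, 1e6, 1e6)
  expect_true(is.na(single$p_value))
  expect_false(single$significant)
  expect_true(single$strong)
})

test_that("a planted fourfold change at low dispersion is called strong with high power", {
  set.seed(21)
  n <- 200
  hits <- vapply(seq_len(n), function(i) {
    a <- rnbinom(3, mu = 100, size = 1 / 0.05)
    b <- rnbinom(3, mu = 400, size = 1 / 0.05)
    d <- differential(a, b, rep(1e6, 3), rep(1e6, 3))
    d$strong && d$significant
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("expression_table assembles consistent records", {
  set.seed(30)
  lens <- c(1000L, 2000L, 1500L, 800L)
  counts <- matrix(rnbinom(4 * 6, mu = 50, size = 10), nrow = 4,
                   dimnames = list(paste0("g", 1:4), NULL))
  counts[2, ] <- 0  # silent gene
  tab <- expression_table(counts, lens, rep(c("24h", "48h"), each = 3),
                          lib_sizes = rep(1e6, 6))
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$category[2], "Cat1")
  expect_equal(tab$rpkm_reported_24h[2], 0)
  expect_true(all(tab$category %in% c("Cat1", "Cat2", "Cat3")))
  expect_equal(tab$expressed_24h, tab$log2rpkm_24h >= 1)
  # significant implies p < 0.05; strong implies |lfc| >= 1
  expect_true(all(!tab$significant | tab$p_value < 0.05))
  expect_true(all(!tab$strong | abs(tab$log2fc) >= 1))
  expect_error(expression_table(counts, lens, rep("24h", 6)),
               "per condition")
})

test_that("records_from_rpkm reproduces the categorical machinery without counts", {
  rec <- records_from_rpkm(c("a", "b", "c"), c(0.5, 10, 3), c(30, 0.2, 3.1))
  expect_equal(rec$category, c("Cat2", "Cat2", "Cat3"))
  expect_true(all(is.na(rec$p_value)))
  expect_false(any(rec$significant))
  expect_equal(rec$rpkm_reported_24h, c(0, 10, 3))
})
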