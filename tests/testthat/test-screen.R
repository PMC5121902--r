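test_that("screen aggregation applies the confidence filter to denominators", {
  pr <- data.frame(label = c(rep("Good", 6), rep("Medium", 3), "Bad"),
                   confidence = rep(1, 10))
  rep1 <- aggregate_screen(pr, zprime_values = c(0.6, 0.7))
  expect_equal(rep1$pct_good, 60)
  expect_equal(rep1$pct_good_or_medium, 90)

  pr$confidence[pr$label == "Bad"] <- 0.3   # filtered out
  rep2 <- aggregate_screen(pr, zprime_values = c(0.6, 0.7))
  expect_equal(rep2$pct_good, 100 * 6 / 9)
  expect_equal(rep2$n_filtered, 1)

  all_good <- data.frame(label = rep("Good", 10), confidence = 1)
  expect_equal(aggregate_screen(all_good, 0.6)$pct_good, 100)

  pr$confidence <- 0.1
  expect_error(aggregate_screen(pr, 0.6), "no confident")
})

test_that("guideline verdicts reproduce the worked screen examples", {
  mk <- function(z, good, gm) list(zprime_mean = z, pct_good = good,
                                   pct_good_or_medium = gm)
  # excellent screen: high Z', 100% Good
  v1 <- guideline_verdict(mk(0.65, 100, 100))
  expect_true(v1$pass)
  expect_identical(v1$verdict, "pass")
  # contaminated cells: plate QC fine, blocks terrible
  v2 <- guideline_verdict(mk(0.53, 4.6, 40))
  expect_false(v2$pass)
  expect_identical(v2$verdict, "matrix-level fail")
  # failed positive control with sound response matrices
  v3 <- guideline_verdict(mk(-0.54, 91.7, 95))
  expect_false(v3$pass)
  expect_identical(v3$verdict, "plate-level fail")
})

test_that("improving any guideline input never flips pass to fail", {
  base <- list(zprime_mean = 0.55, pct_good = 65, pct_good_or_medium = 92)
  expect_true(guideline_verdict(base)$pass)
  for (d in list(c(0.2, 0, 0), c(0, 20, 0), c(0, 0, 5))) {
    better <- list(zprime_mean = base$zprime_mean + d[1],
                   pct_good = base$pct_good + d[2],
                   pct_good_or_medium = base$pct_good_or_medium + d[3])
    expect_true(guideline_verdict(better)$pass)
  }
})

test_that("trinomial tail matches exhaustive enumeration for small m", {
  for (m in 1:6) {
    outcomes <- expand.grid(rep(list(c(1, 0, -1)), m))
    sums <- rowSums(outcomes)
    for (d in unique(sums)) {
      exact <- mean(sums >= d)
      # any count decomposition with difference d has the same tail
      n_plus <- max(d, 0); n_minus <- n_plus - d
      n_zero <- m - n_plus - n_minus
      if (n_zero < 0) next
      expect_equal(trinomial_test(n_plus, n_zero, n_minus), exact,
                   tolerance = 1e-12)
    }
  }
})

test_that("trinomial test symmetry and extreme published-scale tails", {
  expect_gte(trinomial_test(10, 5, 10), 0.5)
  # an overwhelming one-sided outcome lands around 1e-63
  p <- trinomial_test(949, 1944, 191)
  expect_lt(log10(p), -62)
  expect_gt(log10(p), -64)
  # normal approximation (large m path) agrees to order of magnitude
  pn <- trinomial_test(949, 1944, 191, max_exact = 100)
  expect_lt(abs(log10(pn) - log10(p)), 1.5)
  expect_error(trinomial_test(0, 0, 0), "no matched pairs")
})

test_that("type-I error of the paired test is controlled under the null", {
  set.seed(16)
  m <- 60
  draws <- stats::rmultinom(2000, m, rep(1 / 3, 3))
  # cache p-values by observed difference: the tail depends only on d
  ds <- draws[1, ] - draws[3, ]
  pd <- vapply(sort(unique(ds)), function(d) {
    np <- max(d, 0); nm <- np - d
    trinomial_test(np, m - np - nm, nm)
  }, 0)
  names(pd) <- sort(unique(ds))
  ps <- pd[as.character(ds)]
  expect_lte(mean(ps < 0.05), 0.06)
})

test_that("paired comparison matches on keys and counts ordinal outcomes", {
  a <- data.frame(cell = rep(c("L1", "L2"), each = 3),
                  pair = rep(c("c1", "c2", "c3"), 2),
                  label = c("Good", "Good", "Medium", "Bad", "Good", "Medium"),
                  confidence = 1)
  b <- a
  b$label <- c("Medium", "Good", "Bad", "Bad", "Bad", "Good")
  cmp <- paired_compare(a, b, keys = c("cell", "pair"), confidence_min = 0)
  expect_equal(cmp$m, 6)
  expect_equal(cmp$n_plus, 3)  # Good>Medium, Medium>Bad, Good>Bad
  expect_equal(cmp$n_zero, 2)
  expect_equal(cmp$n_minus, 1)
  expect_equal(cmp$n_plus + cmp$n_zero + cmp$n_minus, cmp$m)
  # low-confidence rows drop out before matching
  a2 <- a; a2$confidence[1] <- 0.2
  cmp2 <- paired_compare(a2, b, keys = c("cell", "pair"))
  expect_equal(cmp2$m, 5)
  expect_error(paired_compare(a[0, ], b, keys = c("cell", "pair")),
               "no matched pairs")
})

test_that("BH adjustment follows the step-up hand example", {
  expect_equal(bh_adjust(0.02), 0.02)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  p <- c(0.001, 0.02, 0.8, 0.04)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(sort(adj)) >= 0))
  expect_identical(bh_adjust(numeric(0)), numeric(0))
})
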