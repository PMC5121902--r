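test_that("dmso.v re-orients by readout direction", {
  m <- monotone_block()$responses
  m[6, 6] <- 100
  expect_equal(dmso_v(make_block(m)), 100)
  m[6, 6] <- 37.5
  expect_equal(dmso_v(make_block(m)), 37.5)
  m[6, 6] <- 5
  expect_equal(dmso_v(make_block(m, readout = "signal_increasing")), 95)
})

test_that("RSD features match direct arithmetic and its invariances", {
  # hand oracle on {50, 100}: sd = 35.3553, mean = 75 -> 47.14
  x <- c(50, 100)
  expect_equal(100 * sd(x) / mean(x), 47.1405, tolerance = 1e-4)
  n <- 5
  m <- matrix(100, n, n)
  m[seq_len(n - 1), n] <- rep(c(50, 100), 2)   # agent-1 edge
  m[n, seq_len(n - 1)] <- 75                   # flat agent-2 edge
  b <- make_block(m)
  sa <- single_agent_rsds(b)
  expect_equal(unname(sa["sa.min"]), 0)
  expect_equal(unname(sa["sa.max"]), 100 * sd(rep(c(50, 100), 2)) / 75)
  expect_lte(sa["sa.min"], sa["sa.max"])

  # scale invariance: RSD(k x) = RSD(x)
  sub <- matrix(runif(25, 10, 90), 5, 5)
  blk <- function(s) {
    mm <- matrix(100, 6, 6); mm[1:5, 1:5] <- s; make_block(mm)
  }
  expect_equal(submatrix_rsd(blk(sub)), submatrix_rsd(blk(3 * sub)))

  # constant submatrix
  expect_equal(submatrix_rsd(blk(matrix(42, 5, 5))), 0)

  # near-zero mean hits the configurable cap with a warning
  mm <- matrix(100, 6, 6); mm[1:5, 1:5] <- c(rep(c(-1, 1), 12), 0)
  expect_warning(r <- submatrix_rsd(make_block(mm), cap = 500), "cap")
  expect_equal(r, 500)
})

test_that("moran_i equals the brute-force double sum on small grids", {
  brute <- function(g) {
    z <- as.vector(g) - mean(g)
    nr <- nrow(g); nc <- ncol(g); n <- nr * nc
    coord <- expand.grid(r = seq_len(nr), c = seq_len(nc))
    w <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && abs(coord$r[i] - coord$r[j]) +
            abs(coord$c[i] - coord$c[j]) == 1) w[i, j] <- 1
    }
    w <- w / rowSums(w)
    s0 <- sum(w)
    num <- 0
    for (i in seq_len(n)) for (j in seq_len(n))
      num <- num + w[i, j] * z[i] * z[j]
    (n / s0) * num / sum(z^2)
  }
  set.seed(5)
  for (nr in 2:5) for (nc in 2:5) {
    g <- matrix(rnorm(nr * nc), nr, nc)
    expect_equal(moran_i(g), brute(g), tolerance = 1e-12)
  }
})

test_that("moran_i fixed points: checkerboard -1, gradient positive", {
  cb <- outer(1:4, 1:4, function(i, j) ifelse((i + j) %% 2 == 0, 1, -1))
  expect_equal(moran_i(cb), -1)
  grad <- outer(1:4, 1:4, `+`)
  expect_gt(moran_i(grad), 0)
  expect_error(moran_i(matrix(7, 4, 4)), "zero variance")
})

test_that("moran permutation p-value behaves as a test should", {
  ctrl <- fast_ctrl(n_perm = 199)
  grad <- make_block(outer(1:8, 1:8, function(i, j) 5 * (i + j)))
  expect_lte(moran_test(grad, ctrl), 0.01)
  # uniform under the null, within Monte Carlo error
  set.seed(9)
  ps <- replicate(300, moran_test(matrix(rnorm(25), 5, 5),
                                  features_control(n_perm = 99)))
  expect_lt(abs(mean(ps) - 0.5), 0.05)
  expect_true(all(ps >= 1 / 100 & ps <= 1))
  expect_warning(p1 <- moran_test(matrix(1, 5, 5), ctrl), "constant")
  expect_equal(p1, 1)
  # analytic variant agrees in direction
  actrl <- features_control(moran_method = "analytic")
  expect_lt(moran_test(grad, actrl), 0.01)
  set.seed(10)
  expect_gt(moran_test(matrix(rnorm(36), 6, 6), actrl), 0.01)
})

test_that("smoothness p is small for planes, uniform-ish for shuffles, grows with noise", {
  ctrl <- fast_ctrl(n_boot = 999)
  plane <- make_block(outer(1:8, 1:8, function(i, j) 100 - 4 * i - 5 * j))
  expect_lte(smoothness_test(plane, ctrl), 0.01)

  # under a full GCV refit per resample the null p-value is uniform;
  # the fast projection default trades a known mild anticonservatism
  # for a 100x speedup (see the methods vignette)
  set.seed(21)
  ps <- replicate(60, smoothness_test(matrix(runif(36, 0, 100), 6, 6),
                                      features_control(n_boot = 99,
                                                       smooth_refit = TRUE)))
  expect_lt(abs(mean(ps) - 0.5), 0.1)

  # stochastically monotone in added noise
  base <- outer(1:8, 1:8, function(i, j) 100 - 4 * i - 5 * j)
  pv <- sapply(c(2, 15, 45), function(s) {
    set.seed(33)
    mean(replicate(20, smoothness_test(base + rnorm(64, 0, s),
                                       features_control(n_boot = 199,
                                                        seed = 2))))
  })
  expect_true(all(diff(pv) >= 0))
  expect_gt(pv[3], pv[1])
  expect_warning(pc <- smoothness_test(matrix(3, 6, 6), ctrl), "constant")
  expect_equal(pc, 1)
  # refit mode agrees with the projection shortcut on a clear case
  expect_lte(smoothness_test(plane, features_control(n_boot = 99, seed = 1,
                                                     smooth_refit = TRUE)),
             0.01)
})

test_that("mono.v fixed points and antisymmetry", {
  b <- monotone_block()
  expect_identical(mono_v(b), 1)
  anti <- make_block(200 - b$responses)
  expect_identical(mono_v(anti), 0)
  # readout flip mirrors the score
  expect_identical(mono_v(make_block(b$responses,
                                     readout = "signal_increasing")), 0)
  # ties: constant submatrix scores exactly 0.5
  m <- matrix(100, 6, 6); m[1:5, 1:5] <- 50
  expect_equal(mono_v(make_block(m)), 0.5)
  # antisymmetry on tie-free blocks
  set.seed(2)
  for (i in 1:20) {
    m <- matrix(sample(seq_len(1000), 36), 6, 6)
    bb <- make_block(m)
    nb <- make_block(2 * mean(m) - m)
    expect_equal(mono_v(bb) + mono_v(nb), 1)
  }
  # random blocks average 1/2
  set.seed(3)
  mv <- replicate(2000, mono_v(make_block(matrix(runif(36, 0, 100), 6, 6),
                                          check = FALSE)))
  expect_lt(abs(mean(mv) - 0.5), 0.01)
})

test_that("extract_features assembles the canonical 7-vector deterministically", {
  ctrl <- fast_ctrl()
  good <- gen_block("clean_additive", n = 8, seed = 5)$block
  fx <- qc_features(good, ctrl)
  expect_identical(names(fx), c("block_id", MQC_FEATURES))
  expect_equal(fx$dmso.v, 100)
  expect_gt(fx$mono.v, 0.9)
  expect_lte(fx$smoothness.p, 0.05)

  rug <- gen_block("rugged_noise", n = 8,
                   error = error_model(sigma_eps = 0.3), seed = 6)$block
  fr <- qc_features(rug, ctrl)
  expect_gt(fr$smoothness.p, 0.05)
  expect_lt(abs(fr$mono.v - 0.5), 0.25)

  # bit-reproducible under a fixed seed
  expect_identical(qc_features(rug, ctrl), qc_features(rug, ctrl))
})

test_that("Hill fits recover known curves and flag invalid ones", {
  conc <- 1e-6 * 2^(0:-7)
  y <- 0 + (100 - 0) / (1 + (conc / 1e-7)^1)
  fit <- fit_hill(conc, y)
  expect_true(fit$valid)
  expect_equal(fit$ic50, 1e-7, tolerance = 0.01)
  expect_equal(fit$top, 100, tolerance = 0.01)
  expect_equal(fit$slope, 1, tolerance = 0.01)

  expect_false(fit_hill(conc, rep(80, length(conc)))$valid)

  # potency far above the tested range cannot give a valid IC50
  y2 <- 100 / (1 + (conc / (max(conc) * 10))^2)
  expect_false(fit_hill(conc, y2)$valid)
})

test_that("legacy heuristic score counts violated criteria", {
  ctrl <- fast_ctrl()
  clean <- gen_block("clean_additive", n = 8, seed = 11)$block
  q <- mott_qc(clean, control = ctrl)
  expect_equal(q$score, 0)

  # flat dead block: every criterion fails
  dead <- make_block(matrix(20, 8, 8) + 0, check = TRUE)
  suppressWarnings(qd <- mott_qc(dead, control = ctrl))
  expect_true(all(qd$violated))
  expect_equal(qd$score, 25)

  # score is monotone in the weights of violated criteria
  suppressWarnings(q2 <- mott_qc(dead, weights = c(10, 5, 5, 5, 5),
                                 control = ctrl))
  expect_gte(q2$score, qd$score)
})
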