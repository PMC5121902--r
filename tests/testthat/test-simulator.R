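test_that("generated blocks are valid and seed-deterministic", {
  for (kind in c("clean_additive", "synergistic", "antagonistic",
                 "rugged_noise", "drifted", "dead_control", "bell_shaped")) {
    g <- gen_block(kind, n = 6, error = error_model(sigma_eps = 0.05),
                   seed = 20)
    expect_identical(validate_block(g$block), character(0))
  }
  a <- gen_block("synergistic", n = 8,
                 error = error_model(sigma_eps = 0.1), seed = 77)
  b <- gen_block("synergistic", n = 8,
                 error = error_model(sigma_eps = 0.1), seed = 77)
  expect_identical(a$block$responses, b$block$responses)
})

test_that("noiseless blocks carry exactly their designed Bliss deviation", {
  for (kind in c("clean_additive", "synergistic", "antagonistic")) {
    g <- gen_block(kind, n = 10, error = error_model(), seed = 1)
    expect_equal(bliss_dbnorm(g$block)$dbnorm, g$designed_delta,
                 tolerance = 1e-12)
  }
  g0 <- gen_block("clean_additive", n = 10, error = error_model())
  expect_identical(g0$designed_delta, 0)
  gs <- gen_block("synergistic", n = 10, error = error_model())
  expect_lt(gs$designed_delta, 0)    # more killing than Bliss
  ga <- gen_block("antagonistic", n = 10, error = error_model())
  expect_gt(ga$designed_delta, 0)
})

test_that("archetypes hit their intended failure channels", {
  dead <- gen_block("dead_control", n = 8, seed = 2)
  expect_lt(dmso_v(dead$block), 50)
  expect_identical(dead$label, "Bad")

  good <- gen_block("clean_additive", n = 8,
                    error = error_model(sigma_eps = 0.02), seed = 3)
  expect_identical(good$label, "Good")
  expect_gt(mono_v(good$block), 0.9)

  med <- gen_block("clean_additive", n = 8,
                   error = error_model(sigma_eps = 0.10), seed = 4)
  expect_identical(med$label, "Medium")

  bell <- gen_block("bell_shaped", n = 10, error = error_model(), seed = 5)
  sa <- mqc:::single_agent_responses(bell$block)
  # viability rises again at the top doses: non-monotone single agent
  expect_gt(sa$agent1[1], min(sa$agent1))
})

test_that("full random replacement centers DBNorm at 1/4", {
  sim <- simulate_dbnorm(n_blocks = 800, error = error_model(p_random = 1),
                         seed = 9)
  expect_lt(abs(sim$mean - 0.25), 0.02)
})

test_that("small block-level variation keeps DBNorm symmetric, large well noise skews it", {
  sym <- simulate_dbnorm(n_blocks = 400,
                         error = error_model(sigma_db = 0.05), seed = 10)
  expect_lt(abs(sym$skewness), 0.35)
  expect_lt(abs(sym$sd - 0.05), 0.01)

  # on a low-activity block population the zero-inhibition clamp turns
  # growing well noise into growing positive (antagonism-ward) skew
  sk <- sapply(c(0.02, 0.1, 0.3), function(s)
    simulate_dbnorm(n_blocks = 400, error = error_model(sigma_eps = s),
                    seed = 11, emax = c(0.02, 0.3))$skewness)
  expect_true(all(diff(sk) > 0))
  expect_gt(sk[3], 0)
  # heavy error also pushes the center toward apparent antagonism
  m3 <- simulate_dbnorm(n_blocks = 300,
                        error = error_model(sigma_eps = 0.3),
                        seed = 12, emax = 0.3)
  expect_gt(m3$mean, 0.05)
})

test_that("screens assemble with the left-control layout and truth table", {
  sc <- gen_screen(n_plates = 3, error = error_model(sigma_eps = 0.02),
                   seed = 13)
  expect_equal(nrow(sc$truth), 3 * 12)
  p <- sc$plates[[1]]
  expect_equal(sum(p$wells$role %in% c("neg", "pos")), 128)
  expect_true(all(p$wells$col[p$wells$role != "sample"] <= 4))
  # every block complete and valid after normalization
  blocks <- deconvolute_blocks(normalize_plate(p))
  expect_length(blocks, 12)
  expect_true(all(vapply(blocks, function(b)
    length(validate_block(b)) == 0, TRUE)))
})

test_that("drifted screens look fine at plate level but degrade with column", {
  sc <- gen_screen(n_plates = 2, error = error_model(drift = 3), seed = 14)
  tab <- plate_qc_table(sc$plates)
  expect_true(all(tab$zprime > 0.5))
  # the drift offset at each block position lowers dmso.v monotonically
  p <- normalize_plate(sc$plates[[1]])
  blocks <- deconvolute_blocks(p)
  w <- p$wells[!is.na(p$wells$block_id), ]
  left <- vapply(split(w$col, w$block_id), min, 0)
  dmso <- vapply(blocks, function(b) dmso_v(b), 0)
  ord <- names(sort(left))
  drift_cols <- sort(unique(left))
  mean_by_col <- vapply(drift_cols, function(cc)
    mean(dmso[names(left)[left == cc]]), 0)
  expect_true(all(diff(mean_by_col) > 0))  # dmso.v drifts away from 100
  expect_true(all(sc$truth$label[sc$truth$drift_offset >= 20] == "Bad"))
})
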