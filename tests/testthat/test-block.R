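test_that("block construction enforces the checkerboard geometry", {
  b <- monotone_block()
  expect_s3_class(b, "response_block")
  expect_identical(validate_block(b), character(0))

  # ascending ladder is flagged, not silently accepted
  m <- b$responses
  expect_error(response_block(m, rev(dose_ladder(6)), dose_ladder(6)),
               "descending")
  v <- validate_block(response_block(m, rev(dose_ladder(6)), dose_ladder(6),
                                     check = FALSE))
  expect_true(any(grepl("not strictly descending", v)))

  # non-finite response names its coordinates
  m2 <- m; m2[2, 3] <- NaN
  v2 <- validate_block(make_block(m2, check = FALSE))
  expect_true(any(grepl("\\(2,3\\)", v2)))

  # zero-dose edge must be zero
  v3 <- validate_block(response_block(m, dose_ladder(6),
                                      c(32, 16, 8, 4, 2, 1), check = FALSE))
  expect_true(any(grepl("zero-dose", v3)))
})

test_that("submatrix and single-agent accessors slice the right wells", {
  n <- 6
  m <- matrix(0, n, n)
  m[seq_len(n - 1), seq_len(n - 1)] <- 1  # combination field
  m[seq_len(n - 1), n] <- 2               # agent-1 column
  m[n, seq_len(n - 1)] <- 3               # agent-2 row
  m[n, n] <- 4                            # DMSO corner
  b <- make_block(m)
  expect_true(all(mqc:::combo_submatrix(b) == 1))
  sa <- mqc:::single_agent_responses(b)
  expect_true(all(sa$agent1 == 2) && all(sa$agent2 == 3))
  expect_equal(b$responses[n, n], 4)
})

test_that("block CSV round-trips losslessly", {
  blocks <- list(monotone_block(), bliss_block(5))
  blocks[[1]]$block_id <- "a"; blocks[[2]]$block_id <- "b"
  path <- tempfile(fileext = ".csv")
  write_blocks(blocks, path)
  back <- read_blocks(path)
  expect_equal(back$a$responses, blocks[[1]]$responses)
  expect_equal(back$b$conc1, blocks[[2]]$conc1)
  # header is part of the contract
  d <- read.csv(path)
  expect_identical(names(d),
                   c("block_id", "row", "col", "conc1", "conc2", "response"))
  names(d)[3] <- "column"
  path2 <- tempfile(fileext = ".csv")
  write.csv(d, path2, row.names = FALSE)
  expect_error(read_blocks(path2), "header mismatch")
})

test_that("well labels cover 1536-well coordinates both ways", {
  expect_identical(well_label(1, 1), "A01")
  expect_identical(well_label(27, 10), "AA10")
  expect_identical(well_label(32, 48), "AF48")
  xy <- well_coords(c("A01", "AA10", "AF48"))
  expect_equal(xy$row, c(1, 27, 32))
  expect_equal(xy$col, c(1, 10, 48))
})

test_that("plate normalization is the affine percent-of-control map", {
  w <- data.frame(row = 1:4, col = 1,
                  signal = c(200, 200, 0, 50),
                  role = c("neg", "neg", "pos", "sample"))
  w$signal[3] <- 0
  p <- plate("p1", c(16, 24), w)
  st <- control_stats(neg = c(200, 200), pos = c(0, 0))
  np <- normalize_plate(p, st)
  expect_equal(np$wells$signal, c(100, 100, 0, 25))
  # order-preserving and unclipped
  w2 <- w; w2$signal[4] <- 250
  np2 <- normalize_plate(plate("p2", c(16, 24), w2), st)
  expect_equal(np2$wells$signal[4], 125)
  expect_error(normalize_plate(p, control_stats(neg = c(5, 5), pos = c(5, 5))),
               "degenerate")
})

test_that("deconvolution reproduces simulator blocks bit-identically", {
  sc <- gen_screen(n_plates = 1, error = error_model(), seed = 3)
  p <- sc$plates[[1]]
  # zero noise on samples: plate holds the normalized responses directly
  blocks <- deconvolute_blocks(p)
  expect_length(blocks, 12)
  src <- p$wells[!is.na(p$wells$block_id), ]
  one <- src[src$block_id == names(blocks)[1], ]
  got <- blocks[[1]]$responses[cbind(one$block_row, one$block_col)]
  expect_identical(got, one$signal)

  # dropping one well is an error naming block and coordinate
  drop <- which(!is.na(p$wells$block_id))[1]
  bad <- p
  bad$wells <- bad$wells[-drop, ]
  expect_error(deconvolute_blocks(bad), "incomplete block .*missing well")
})

test_that("plate/layout CSV round-trips through the readers", {
  sc <- gen_screen(n_plates = 2, error = error_model(sigma_eps = 0.05),
                   seed = 4)
  pp <- tempfile(fileext = ".csv"); lp <- tempfile(fileext = ".csv")
  write_plates(sc$plates, pp, lp)
  back <- read_plates(pp, lp)
  expect_length(back, 2)
  orig <- sc$plates[[1]]$wells
  got <- back[["P01"]]$wells
  key <- order(got$row, got$col)
  okey <- order(orig$row, orig$col)
  expect_equal(got$signal[key], orig$signal[okey])
  expect_equal(got$role[key], orig$role[okey])
})
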