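# Small fixture builders shared across test files.

# bare block from a response matrix, default ladders
make_block <- function(m, readout = "signal_decreasing", check = TRUE) {
  n <- nrow(m)
  response_block(m, dose_ladder(n), dose_ladder(n),
                 readout_direction = readout, check = check)
}

# strictly monotone 6x6 surface: response rises with index, i.e. falls
# with dose, the expected viability shape
monotone_block <- function(n = 6) {
  make_block(outer(seq_len(n), seq_len(n), function(i, j) 10 * (i + j)))
}

# block lying exactly on the Bliss surface built from its own edges
bliss_block <- function(n = 6, fA = NULL, fB = NULL) {
  if (is.null(fA)) fA <- seq(0.9, 0.1, length.out = n - 1)
  if (is.null(fB)) fB <- seq(0.8, 0.05, length.out = n - 1)
  V <- matrix(0, n, n)
  V[seq_len(n - 1), seq_len(n - 1)] <-
    100 * (1 - outer(fA, fB, function(a, b) a + b - a * b))
  V[seq_len(n - 1), n] <- 100 * (1 - fA)
  V[n, seq_len(n - 1)] <- 100 * (1 - fB)
  V[n, n] <- 100
  make_block(V)
}

fast_ctrl <- function(seed = 1, n_perm = 199, n_boot = 199) {
  features_control(n_perm = n_perm, n_boot = n_boot, seed = seed)
}

# quick separable 3-class feature set for classifier mechanics tests
toy_features <- function(n_per_class = 30, seed = 1, sd = 0.5) {
  set.seed(seed)
  centers <- list(Good = c(0, 0), Medium = c(3, 0), Bad = c(0, 3))
  x <- do.call(rbind, lapply(names(centers), function(k)
    cbind(rnorm(n_per_class, centers[[k]][1], sd),
          rnorm(n_per_class, centers[[k]][2], sd))))
  fx <- as.data.frame(matrix(0, nrow(x), 7))
  names(fx) <- MQC_FEATURES
  fx$dmso.v <- x[, 1]
  fx$mono.v <- x[, 2]
  fx$sa.min <- rnorm(nrow(x))   # uninformative filler features
  fx$sa.max <- fx$sa.min + abs(rnorm(nrow(x)))
  fx$sa.matrix <- rnorm(nrow(x))
  fx$moran.p <- runif(nrow(x))
  fx$smoothness.p <- runif(nrow(x))
  list(x = fx, y = rep(names(centers), each = n_per_class))
}
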