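# Fixtures are generated in code, never stored. All generators are
# deterministic under their seed argument.

flip_bits <- function(x, p) {
  ifelse(stats::runif(length(x)) < p, 1 - x, x)
}

# Binary copy chain X -> Y -> Z, each hop a one-sample lag with optional
# symmetric flip noise. With l_source = 2 the source past reaches the
# causally relevant lag of the two-hop path.
make_copy_chain <- function(n, flip = 0, seed = 1) {
  withr::with_seed(seed, {
    x <- stats::rbinom(n, 1, 0.5)
    y <- flip_bits(c(0, x[-n]), flip)
    z <- flip_bits(c(0, y[-n]), flip)
    multichannel_series(rbind(x, y, z), c("X", "Y", "Z"))
  })
}

# XOR target: y_{t+1} = x1_t xor x2_t with iid fair-bit parents — zero
# bivariate TE from either parent, 1 bit conditionally.
make_xor <- function(n, seed = 1) {
  withr::with_seed(seed, {
    x1 <- stats::rbinom(n, 1, 0.5)
    x2 <- stats::rbinom(n, 1, 0.5)
    y <- c(0, as.numeric(x1 != x2)[-n])
    multichannel_series(rbind(x1, x2, y), c("X1", "X2", "Y"))
  })
}

make_bits <- function(n, k = 2, seed = 1, labels = NULL) {
  withr::with_seed(seed, {
    multichannel_series(matrix(stats::rbinom(n * k, 1, 0.5), nrow = k),
                        labels %||% paste0("B", seq_len(k)))
  })
}

# Stable bivariate Gaussian VAR(1) with known X -> Y coupling.
make_var_pair <- function(n, a_xy = 0.4, seed = 1) {
  withr::with_seed(seed, {
    x <- numeric(n); y <- numeric(n)
    ex <- stats::rnorm(n); ey <- stats::rnorm(n)
    for (t in 2:n) {
      x[t] <- 0.5 * x[t - 1] + ex[t]
      y[t] <- a_xy * x[t - 1] + 0.3 * y[t - 1] + ey[t]
    }
    multichannel_series(rbind(x, y), c("X", "Y"))
  })
}

# Linear VAR(1) chain A -> B -> C with self terms.
make_linear_chain <- function(n, a = 0.5, seed = 1) {
  withr::with_seed(seed, {
    v <- matrix(0, 3, n)
    eps <- matrix(stats::rnorm(3 * n), 3, n)
    for (t in 2:n) {
      v[1, t] <- 0.3 * v[1, t - 1] + eps[1, t]
      v[2, t] <- a * v[1, t - 1] + 0.3 * v[2, t - 1] + eps[2, t]
      v[3, t] <- a * v[2, t - 1] + 0.3 * v[3, t - 1] + eps[3, t]
    }
    multichannel_series(v, c("A", "B", "C"))
  })
}

# VAR(2) pair for order-selection tests.
make_var2 <- function(n, seed = 1) {
  withr::with_seed(seed, {
    v <- matrix(0, 2, n)
    eps <- matrix(stats::rnorm(2 * n), 2, n)
    for (t in 3:n) {
      v[1, t] <- 0.4 * v[1, t - 1] - 0.35 * v[1, t - 2] + eps[1, t]
      v[2, t] <- 0.4 * v[1, t - 2] + 0.3 * v[2, t - 1] + eps[2, t]
    }
    multichannel_series(v, c("X", "Y"))
  })
}

make_white <- function(n, k = 2, seed = 1) {
  withr::with_seed(seed, {
    multichannel_series(matrix(stats::rnorm(n * k), nrow = k),
                        paste0("W", seq_len(k)))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small synthetic EEG subject for pipeline tests.
small_paradigm <- function(seed = 1, n_runs = 1L) {
  paradigm_spec(n_stimuli = 20L, n_targets = 8L, n_runs = n_runs, seed = seed)
}
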