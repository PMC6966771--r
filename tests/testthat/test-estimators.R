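# Discretization ------------------------------------------------------------

test_that("discretize handles constant input, single bins and degeneracy", {
  const <- multichannel_series(matrix(5, 1, 100), "c")
  expect_true(all(discretize(const, 4, "equal_width") == 0L))
  expect_error(discretize(const, 4, "quantile"), "'c'")
  rand <- make_white(100, 2, seed = 1)
  expect_true(all(discretize(rand, 1) == 0L))
})

test_that("quantile bins give near-equal occupancy on continuous data", {
  s <- make_white(100000, 1, seed = 7)
  sym <- discretize(s, 4, "quantile")
  freq <- tabulate(sym + 1L, 4) / 100000
  expect_true(all(abs(freq - 0.25) <= 0.01))
  expect_true(all(sym >= 0 & sym < 4))
})

test_that("equal-width bins cover the observed range", {
  s <- multichannel_series(matrix(seq(0, 1, length.out = 100), 1), "x")
  sym <- discretize(s, 5, "equal_width")
  expect_identical(sort(unique(as.vector(sym))), 0:4)
})

# Embedding ------------------------------------------------------------------

test_that("embed_series matches hand-enumerated indices", {
  s <- multichannel_series(matrix(1:5, 1), "X")
  emb <- embed_series(s, embedding_spec(1, 1, 1), target = "X", sources = "X")
  expect_identical(nrow(emb$target_past), 4L)
  expect_identical(emb$present[1], 2)
  expect_equal(emb$target_past[1, 1], 1, ignore_attr = TRUE)
  expect_equal(emb$source_past[1, 1], 1, ignore_attr = TRUE)

  s2 <- multichannel_series(matrix(rnorm(40), 1), "X")
  emb2 <- embed_series(s2, embedding_spec(2, 1, 1), target = "X")
  expect_identical(length(emb2$present), 40L - 2L)

  emb3 <- embed_series(s2, embedding_spec(1, 1, 3), target = "X")
  expect_identical(emb3$time_index[1], 4L)  # first present is 0-based sample 3
})

test_that("embed_series rejects too-short series", {
  s <- multichannel_series(matrix(1:4, 1), "X")
  expect_error(embed_series(s, embedding_spec(5, 1, 1), "X"), "too short")
})

# Transfer entropy -----------------------------------------------------------

test_that("plug-in TE vanishes for independent processes and finds the copy channel", {
  ind <- make_bits(20000, 2, seed = 3)
  expect_lte(transfer_entropy(ind, "B1", "B2", n_bins = 2)$te, 0.01)

  cp <- withr::with_seed(5, {
    x <- rbinom(20000, 1, 0.5)
    multichannel_series(rbind(x, c(0, x[-20000])), c("X", "Y"))
  })
  fwd <- transfer_entropy(cp, "X", "Y", n_bins = 2)
  bwd <- transfer_entropy(cp, "Y", "X", n_bins = 2)
  expect_equal(fwd$te, 1, tolerance = 0.02)
  expect_lte(bwd$te, 0.05)            # asymmetry
  expect_equal(fwd$te, fwd$h2 - fwd$h1)
  expect_identical(fwd$n_effective, 19999L)
})

test_that("gaussian TE matches an independent OLS oracle to 1e-6", {
  s <- make_var_pair(5000, a_xy = 0.4, seed = 11)
  te <- transfer_entropy(s, "X", "Y", estimator = "gaussian")
  y <- s$values["Y", ]; x <- s$values["X", ]
  pres <- 2:5000
  r1 <- stats::lm(y[pres] ~ y[pres - 1])
  r2 <- stats::lm(y[pres] ~ y[pres - 1] + x[pres - 1])
  oracle <- 0.5 * log2(sum(r1$residuals^2) / sum(r2$residuals^2))
  expect_equal(te$te, oracle, tolerance = 1e-6)
})

test_that("TE validates inputs", {
  s <- make_bits(100, 2, seed = 1)
  expect_error(transfer_entropy(s, "B1", "B1"), "differ")
  expect_error(transfer_entropy(s, "B1", "B2", n_bins = 1), "n_bins >= 2")
  expect_error(conditional_transfer_entropy(s, "B1", "B2", conditions = "B1"),
               "condition")
})

test_that("plug-in warns when the joint space dwarfs the sample", {
  s <- make_white(120, 3, seed = 2)
  expect_warning(
    conditional_transfer_entropy(s, "W1", "W2", "W3",
                                 spec = embedding_spec(2, 2, 1), n_bins = 5),
    "joint space")
})

# Conditional TE -------------------------------------------------------------

test_that("empty condition set reduces exactly to TE", {
  s <- make_var_pair(800, seed = 21)
  a <- transfer_entropy(s, "X", "Y", n_bins = 3)
  b <- conditional_transfer_entropy(s, "X", "Y", conditions = NULL, n_bins = 3)
  expect_identical(a$te, b$te)
  g1 <- transfer_entropy(s, "X", "Y", estimator = "gaussian")
  g2 <- conditional_transfer_entropy(s, "X", "Y", estimator = "gaussian")
  expect_identical(g1$te, g2$te)
})

test_that("conditioning screens the indirect edge of a Markov chain", {
  ch <- make_copy_chain(20000, flip = 0, seed = 31)
  spec2 <- embedding_spec(2, 2, 1)
  te_xz <- transfer_entropy(ch, "X", "Z", spec = spec2, n_bins = 2)
  cte_xz <- conditional_transfer_entropy(ch, "X", "Z", "Y", spec = spec2,
                                         n_bins = 2)
  expect_gte(te_xz$te, 0.5)
  expect_lte(cte_xz$te, 0.02)
})

test_that("XOR synergy: invisible bivariately, 1 bit conditionally", {
  s <- make_xor(20000, seed = 41)
  expect_lte(transfer_entropy(s, "X1", "Y", n_bins = 2)$te, 0.02)
  cte <- conditional_transfer_entropy(s, "X1", "Y", "X2", n_bins = 2)
  expect_equal(cte$te, 1, tolerance = 0.02)
})

# Surrogate testing ----------------------------------------------------------

test_that("surrogate test hits the p-value floor on a strong coupling", {
  cp <- withr::with_seed(6, {
    x <- rbinom(3000, 1, 0.5)
    multichannel_series(rbind(x, c(0, x[-3000])), c("X", "Y"))
  })
  st <- surrogate_test(cp, "X", "Y", n_bins = 2, n_perm = 99, seed = 9)
  expect_equal(st$p_value, 0.01)
  expect_true(st$significant)
  expect_length(st$surrogate_values, 99)
  # p-value invariant
  expect_equal(st$p_value,
               (1 + sum(st$surrogate_values >= st$observed)) / (1 + st$n_perm))
})

test_that("surrogate test is deterministic under a fixed seed", {
  s <- make_var_pair(600, seed = 13)
  a <- surrogate_test(s, "X", "Y", n_perm = 29, seed = 77)
  b <- surrogate_test(s, "X", "Y", n_perm = 29, seed = 77)
  expect_identical(a, b)
})

test_that("surrogate test maintains its type-I error rate", {
  # true rate is ~0.043 (1,000-rep estimate; slightly conservative from ties)
  rej <- vapply(1:200, function(i) {
    s <- make_bits(500, 2, seed = 20000 + i)
    surrogate_test(s, "B1", "B2", n_bins = 2, n_perm = 19, alpha = 0.05,
                   seed = i)$significant
  }, logical(1))
  expect_lte(abs(mean(rej) - 0.05), 0.04)
})

test_that("surrogate test validates n_perm and supports custom statistics", {
  s <- make_bits(200, 2, seed = 4)
  expect_error(surrogate_test(s, "B1", "B2", n_perm = 10), "19")
  st <- surrogate_test(s, "B1", "B2", n_perm = 19, seed = 3,
                       statistic = function(series, src, tgt, cond) {
                         stats::cor(series$values[1, ], series$values[2, ])
                       })
  expect_s3_class(st, "surrogate_result")
})

# Property: TE >= 0 for the plug-in estimator (up to tiny numerical slack)
test_that("plug-in TE is non-negative across random fixtures", {
  for (i in 1:20) {
    s <- make_white(300, 3, seed = 500 + i)
    te <- conditional_transfer_entropy(s, "W1", "W2", "W3", n_bins = 3)
    expect_gte(te$te, -1e-12)
  }
})
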