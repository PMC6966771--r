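# MVAR fitting ---------------------------------------------------------------

test_that("fit_mvar recovers known VAR(1) coefficients", {
  s <- make_var_pair(5000, a_xy = 0.4, seed = 1)
  fit <- fit_mvar(s, 1)
  A <- fit$coefficients[[1]]
  # standard errors on n = 5000 are ~0.014; allow 3 of them
  expect_lte(abs(A["X", "X"] - 0.5), 0.045)
  expect_lte(abs(A["X", "Y"] - 0.4), 0.045)
  expect_lte(abs(A["Y", "Y"] - 0.3), 0.045)
  expect_lte(abs(A["Y", "X"]), 0.045)
  Sig <- fit$residual_covariance
  expect_equal(Sig, t(Sig))
  expect_true(all(eigen(Sig, only.values = TRUE)$values > 0))
})

test_that("fit_mvar on white noise yields near-zero coefficients", {
  s <- make_white(5000, 2, seed = 2)
  fit <- fit_mvar(s, 1)
  expect_true(all(abs(fit$coefficients[[1]]) <= 0.1))
})

test_that("fit_mvar rejects infeasible orders and singular designs", {
  s <- make_white(30, 2, seed = 3)
  expect_error(fit_mvar(s, 30), "too short")
  dup <- multichannel_series(rbind(s$values[1, ], s$values[1, ] * 2),
                             c("a", "b"))
  expect_error(fit_mvar(dup, 1), "singular|rank")
})

test_that("AIC order selection recovers a VAR(2) and penalizes white noise", {
  hits <- vapply(1:50, function(i) {
    select_order_aic(make_var2(2000, seed = 100 + i), max_order = 6)
  }, integer(1))
  expect_gte(mean(hits == 2L), 0.8)
  expect_identical(select_order_aic(make_var2(500, seed = 1), max_order = 1), 1L)
  expect_identical(select_order_aic(make_white(5000, 2, seed = 5), 4), 1L)
})

# GCA network ----------------------------------------------------------------

test_that("GCA recovers a linear chain exactly", {
  s <- make_linear_chain(2000, seed = 3)
  net <- infer_gca_network(s, inference_params(seed = 1))
  truth <- matrix(0L, 3, 3, dimnames = list(s$labels, s$labels))
  truth["A", "B"] <- 1L; truth["B", "C"] <- 1L
  expect_identical(unname(net$binary), unname(truth))
  expect_true(all(diag(net$weights) == 0))
})

test_that("gaussian TE equals the GCA statistic over 2*ln(2) on linear VARs", {
  for (i in 1:5) {
    s <- make_var_pair(1500, a_xy = 0.3, seed = 40 + i)
    net <- infer_gca_network(s, inference_params(max_order = 1, seed = 1))
    te <- transfer_entropy(s, "X", "Y",
                           spec = embedding_spec(net$order, net$order, 1),
                           estimator = "gaussian")
    expect_equal(te$te, net$weights["X", "Y"] / (2 * log(2)), tolerance = 1e-6)
  }
})

test_that("gaussian TE equals half the log-variance-ratio from fit_mvar fits", {
  # cross-module oracle: full bivariate MVAR vs univariate AR, in nats
  s <- make_var_pair(3000, seed = 55)
  full <- fit_mvar(s, 1)
  tgt_only <- multichannel_series(s$values["Y", , drop = FALSE], "Y")
  restr <- fit_mvar(tgt_only, 1)
  gc_nats <- log(restr$residual_covariance[1, 1] /
                   full$residual_covariance["Y", "Y"])
  te <- transfer_entropy(s, "X", "Y", estimator = "gaussian")
  expect_equal(te$te * log(2), gc_nats / 2, tolerance = 1e-6)
})

# BVTE network ---------------------------------------------------------------

test_that("BVTE finds chain edges including the spurious cascade edge", {
  s <- make_copy_chain(2000, flip = 0.1, seed = 8)
  p <- inference_params(embedding = embedding_spec(2, 2, 1), n_bins = 2,
                        n_perm = 99, seed = 5)
  net <- infer_bvte_network(s, p)
  expect_identical(net$binary["X", "Y"], 1L)
  expect_identical(net$binary["Y", "Z"], 1L)
  expect_identical(net$binary["X", "Z"], 1L)  # two-hop cascade flagged
  expect_identical(net$binary["Z", "X"], 0L)
})

test_that("BVTE keeps its false-edge rate near alpha on independent channels", {
  rates <- vapply(1:50, function(i) {
    s <- make_bits(400, 3, seed = 2000 + i)
    p <- inference_params(n_bins = 2, n_perm = 19, alpha = 0.05, seed = i)
    mean(infer_bvte_network(s, p)$binary[row(diag(3)) != col(diag(3))])
  }, numeric(1))
  expect_lte(abs(mean(rates) - 0.05), 0.04)
})

test_that("network inference needs at least two processes", {
  s1 <- multichannel_series(matrix(rnorm(100), 1), "only")
  expect_error(infer_bvte_network(s1), "2 processes")
  expect_error(infer_mte_network(s1), "2 processes")
  expect_error(infer_gca_network(s1), "2 processes")
})

# MTE network ----------------------------------------------------------------

test_that("MTE prunes the cascade edge of a chain", {
  s <- make_copy_chain(2000, flip = 0.1, seed = 9)
  p <- inference_params(embedding = embedding_spec(2, 2, 1), n_bins = 2,
                        n_perm = 99, seed = 6)
  net <- infer_mte_network(s, p)
  expect_identical(net$binary["X", "Y"], 1L)
  expect_identical(net$binary["Y", "Z"], 1L)
  expect_identical(net$binary["X", "Z"], 0L)  # screened off by Y
})

test_that("MTE captures the synergistic XOR parents", {
  s <- make_xor(20000, seed = 10)
  p <- inference_params(n_bins = 2, n_perm = 99, seed = 7)
  net <- infer_mte_network(s, p)
  expect_identical(net$binary["X1", "Y"], 1L)
  expect_identical(net$binary["X2", "Y"], 1L)
  expect_gte(net$weights["X1", "Y"], 0.9)
  expect_gte(net$weights["X2", "Y"], 0.9)
})

test_that("MTE returns an empty network on independent channels", {
  # n_perm = 199 so surrogates can resolve alpha = 0.01 with headroom
  empty <- vapply(1:50, function(i) {
    s <- make_bits(400, 3, seed = 3000 + i)
    p <- inference_params(n_bins = 2, n_perm = 199, alpha = 0.01, seed = i)
    sum(infer_mte_network(s, p)$binary) == 0
  }, logical(1))
  expect_gte(mean(empty), 0.9)
})

test_that("MTE produces no more chain false positives than BVTE", {
  fp_of <- function(net) {
    truth <- matrix(0, 3, 3); truth[1, 2] <- truth[2, 3] <- 1
    cc <- confusion_counts(net$binary, truth)
    cc$fp
  }
  fps <- t(vapply(1:20, function(i) {
    s <- make_copy_chain(1500, flip = 0.1, seed = 4000 + i)
    p <- inference_params(embedding = embedding_spec(2, 2, 1), n_bins = 2,
                          n_perm = 19, seed = i)
    c(mte = fp_of(infer_mte_network(s, p)),
      bvte = fp_of(infer_bvte_network(s, p)))
  }, c(mte = 0, bvte = 0)))
  expect_lte(mean(fps[, "mte"]), mean(fps[, "bvte"]))
})

# Shared invariants -----------------------------------------------------------

test_that("all methods return valid, deterministic networks", {
  s <- make_linear_chain(600, seed = 12)
  p <- inference_params(n_perm = 19, seed = 99)
  for (m in c("gca", "bvte", "mte")) {
    n1 <- mtenet:::infer_by_method(s, m, p)
    n2 <- mtenet:::infer_by_method(s, m, p)
    expect_identical(n1, n2)                     # determinism
    expect_true(all(diag(n1$weights) == 0))
    expect_true(all(diag(n1$binary) == 0))
    if (m != "gca") {
      expect_true(all(n1$weights[n1$binary == 1] > 0))
      expect_true(all(n1$weights >= 0))
    }
  }
})
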