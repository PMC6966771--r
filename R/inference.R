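#' Inference parameters
#'
#' Bundles everything the three network-inference routines need: the
#' embedding, the estimator, surrogate-test settings, the Granger order
#' search bound, and the root seed for reproducibility.
#'
#' @param embedding an [embedding_spec()].
#' @param estimator `"plugin"` or `"gaussian"` (transfer-entropy methods).
#' @param n_bins plug-in histogram bins.
#' @param n_perm surrogates per significance test (>= 19).
#' @param alpha per-test significance level in (0, 1).
#' @param max_order upper bound of the AIC order search for Granger analysis.
#' @param seed integer root seed; all surrogate substreams derive from it.
#' @param max_sources cap on selected sources per target in the greedy
#'   multivariate search (default: all other processes).
#' @param synergy_pairs if `TRUE` (default), a target for which single-source
#'   forward selection finds nothing is re-examined with jointly tested
#'   source pairs under a max-statistic surrogate null, so purely synergistic
#'   parent sets (e.g. an XOR target) are not missed.
#' @return An `inference_params` object.
#' @export
inference_params <- function(embedding = embedding_spec(), estimator = "plugin",
                             n_bins = 3L, n_perm = 199L, alpha = 0.05,
                             max_order = 5L, seed = 1L, max_sources = NULL,
                             synergy_pairs = TRUE) {
  stopifnot(inherits(embedding, "embedding_spec"))
  estimator <- match.arg(estimator, c("plugin", "gaussian"))
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  if (max_order < 1L) stop("max_order must be >= 1")
  structure(list(embedding = embedding, estimator = estimator,
                 n_bins = as.integer(n_bins), n_perm = as.integer(n_perm),
                 alpha = alpha, max_order = as.integer(max_order),
                 seed = seed, max_sources = max_sources,
                 synergy_pairs = isTRUE(synergy_pairs)),
            class = "inference_params")
}

#' Directed network container
#'
#' Square weighted and binary adjacency matrices with the fixed orientation
#' row = source, column = target. Weights are bits for transfer-entropy
#' methods and log variance ratios for Granger analysis; the binary matrix
#' flags significant edges.
#'
#' @param weights,binary square numeric/0-1 matrices (same shape).
#' @param labels node identifiers.
#' @param method one of `"gca"`, `"bvte"`, `"mte"`.
#' @param alpha significance level the binary matrix was thresholded at.
#' @return A `directed_network` object.
#' @export
directed_network <- function(weights, binary, labels, method,
                             alpha = NA_real_) {
  weights <- as.matrix(weights); binary <- as.matrix(binary)
  n <- nrow(weights)
  if (ncol(weights) != n || !all(dim(binary) == c(n, n))) {
    stop("weights and binary must be square matrices of the same shape")
  }
  diag(weights) <- 0; diag(binary) <- 0
  binary <- (binary != 0) * 1L
  if (method %in% c("bvte", "mte")) {
    weights[weights < 0] <- 0           # clamp finite-sample negatives
    binary[weights <= 0] <- 0L          # binary support within positive weights
  }
  dimnames(weights) <- dimnames(binary) <- list(labels, labels)
  structure(list(weights = weights, binary = binary, labels = labels,
                 method = method, alpha = alpha),
            class = "directed_network")
}

#' @export
print.directed_network <- function(x, ...) {
  cat(sprintf("<directed_network> %s, %d nodes, %d significant edges (row = source)\n",
              x$method, nrow(x$weights), sum(x$binary)))
  invisible(x)
}

#' Bivariate transfer-entropy network
#'
#' Transfer entropy between every ordered pair of processes, each pair tested
#' for significance with circular-shift surrogates; no conditioning on the
#' remaining processes (so cascade edges and common-driver effects are left
#' in, by design).
#'
#' @param series a [multichannel_series()] with >= 2 processes.
#' @param params an [inference_params()].
#' @return A [directed_network()] with `method = "bvte"`.
#' @export
infer_bvte_network <- function(series, params = inference_params()) {
  n <- n_processes(series)
  if (n < 2L) stop("need at least 2 processes to infer a network")
  W <- matrix(0, n, n); B <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    st <- tryCatch(
      suppressWarnings(surrogate_test(
        series, source = i, target = j, conditions = NULL,
        spec = params$embedding, estimator = params$estimator,
        n_bins = params$n_bins, n_perm = params$n_perm,
        alpha = params$alpha,
        seed = derive_seed(params$seed, "bvte", i, j))),
      error = function(e) stop("pair ", series$labels[i], "->",
                               series$labels[j], ": ", conditionMessage(e)))
    W[i, j] <- st$observed
    B[i, j] <- as.integer(st$significant)
  }
  directed_network(W, B, series$labels, "bvte", params$alpha)
}

# Joint TE from a set of sources into a target (plug-in or gaussian), used by
# the synergy-pair rescue step.
joint_te <- function(vals, srcs, tgt, cnd, spec, estimator, n_bins, shift = NULL) {
  suppressWarnings(
    te_core(vals, tgt, srcs, cnd, spec, estimator, n_bins, shift = shift)$te)
}

#' Multivariate transfer-entropy network
#'
#' Per target: greedy forward selection of relevant sources (each step adds
#' the candidate with maximal conditional TE given the already-selected set,
#' kept only if surrogate-significant), followed by backward pruning (each
#' selected source re-tested conditional on the remaining selected set).
#' Edge weights are the conditional TE of each surviving source given the
#' other survivors. If nothing is selected and `synergy_pairs` is enabled,
#' candidate pairs are tested jointly under a max-statistic surrogate null to
#' capture purely synergistic parents.
#'
#' @inheritParams infer_bvte_network
#' @return A [directed_network()] with `method = "mte"`.
#' @export
infer_mte_network <- function(series, params = inference_params()) {
  n <- n_processes(series)
  if (n < 2L) stop("need at least 2 processes to infer a network")
  spec <- params$embedding
  vals <- if (params$estimator == "plugin") {
    discretize(series, params$n_bins)
  } else series$values
  Tn <- n_samples(series)
  max_k <- params$max_sources %||% (n - 1L)
  W <- matrix(0, n, n); B <- matrix(0L, n, n)

  shift_sig <- function(srcs, tgt, cnd, seed_key) {
    # significance of CTE(srcs -> tgt | cnd) under independent circular shifts
    obs <- joint_te(vals, srcs, tgt, cnd, spec, params$estimator, params$n_bins)
    offs <- draw_offsets(Tn, params$n_perm, length(srcs),
                         derive_seed(params$seed, "mte", tgt, seed_key))
    surr <- numeric(params$n_perm)
    for (b in seq_len(params$n_perm)) {
      surr[b] <- joint_te(vals, srcs, tgt, cnd, spec, params$estimator,
                          params$n_bins, shift = offs[b, ])
    }
    p <- (1 + sum(surr >= obs)) / (1 + params$n_perm)
    list(observed = obs, p = p, significant = p <= params$alpha)
  }

  for (tgt in seq_len(n)) {
    candidates <- setdiff(seq_len(n), tgt)
    selected <- integer(0)
    step <- 0L
    while (length(candidates) && length(selected) < max_k) {
      step <- step + 1L
      cte <- vapply(candidates, function(s) {
        joint_te(vals, s, tgt, selected, spec, params$estimator, params$n_bins)
      }, numeric(1))
      best <- candidates[which.max(cte)]
      res <- shift_sig(best, tgt, selected, paste0("fwd", step))
      if (!res$significant) break
      selected <- c(selected, best)
      candidates <- setdiff(candidates, best)
    }
    if (!length(selected) && params$synergy_pairs && n >= 3L) {
      # synergy rescue: max over jointly-tested pairs, FWER-controlled by a
      # max-statistic surrogate null
      prs <- utils::combn(setdiff(seq_len(n), tgt), 2L)
      obs_all <- apply(prs, 2L, function(pp) {
        joint_te(vals, pp, tgt, integer(0), spec, params$estimator, params$n_bins)
      })
      offs <- draw_offsets(Tn, params$n_perm, n,
                           derive_seed(params$seed, "mte", tgt, "pair"))
      surr_max <- numeric(params$n_perm)
      for (b in seq_len(params$n_perm)) {
        off_all <- offs[b, ]
        surr_max[b] <- max(apply(prs, 2L, function(pp) {
          joint_te(vals, pp, tgt, integer(0), spec, params$estimator,
                   params$n_bins, shift = off_all[pp])
        }))
      }
      p <- (1 + sum(surr_max >= max(obs_all))) / (1 + params$n_perm)
      if (p <= params$alpha) selected <- prs[, which.max(obs_all)]
    }
    if (length(selected) > 1L) {
      # backward pruning: re-test each source given the remaining selected set
      for (s in selected) {
        rest <- setdiff(selected, s)
        res <- shift_sig(s, tgt, rest, paste0("bwd", s))
        if (!res$significant) selected <- setdiff(selected, s)
      }
    }
    for (s in selected) {
      W[s, tgt] <- max(0, joint_te(vals, s, tgt, setdiff(selected, s), spec,
                                   params$estimator, params$n_bins))
      B[s, tgt] <- 1L
    }
  }
  directed_network(W, B, series$labels, "mte", params$alpha)
}

# ---- multivariate autoregressive modelling --------------------------------

mvar_design <- function(values, order, start = order + 1L) {
  Tn <- ncol(values); n <- nrow(values)
  idx <- start:Tn
  X <- matrix(1, length(idx), 1L + n * order)
  for (p in seq_len(order)) {
    X[, (1L + (p - 1L) * n + 1L):(1L + p * n)] <- t(values[, idx - p, drop = FALSE])
  }
  list(X = X, Y = t(values[, idx, drop = FALSE]), idx = idx)
}

#' Fit a multivariate autoregressive (MVAR) model
#'
#' Per-equation ordinary least squares on lagged regressors (with intercept).
#' `coefficients[[p]][i, j]` is the effect of process `i`'s lag-`p` value on
#' process `j`'s present. AIC follows the multivariate form
#' `n_eff * log(det(Sigma)) + 2 * p * n^2`.
#'
#' @param series a [multichannel_series()].
#' @param order lag order `p >= 1`.
#' @return An `mvar_model` with `order`, `coefficients` (list of `n x n`
#'   matrices), `intercepts`, `residual_covariance`, `aic`, `n_eff` and
#'   `residuals`.
#' @export
fit_mvar <- function(series, order) {
  order <- as.integer(order)
  if (order < 1L) stop("order must be >= 1")
  n <- n_processes(series); Tn <- n_samples(series)
  if (Tn <= order * n + 1L) {
    stop("series too short (", Tn, " samples) for an MVAR of order ", order,
         " on ", n, " processes")
  }
  d <- mvar_design(series$values, order)
  qrX <- qr(d$X)
  if (qrX$rank < ncol(d$X)) stop("singular MVAR fit: rank-deficient regressor matrix")
  beta <- qr.coef(qrX, d$Y)
  res <- d$Y - d$X %*% beta
  n_eff <- nrow(d$Y)
  Sigma <- crossprod(res) / n_eff
  Sigma <- (Sigma + t(Sigma)) / 2
  dt <- det(Sigma)
  aic <- if (dt > 0) n_eff * log(dt) + 2 * order * n^2 else -Inf
  coefs <- lapply(seq_len(order), function(p) {
    m <- beta[(1L + (p - 1L) * n + 1L):(1L + p * n), , drop = FALSE]
    dimnames(m) <- list(series$labels, series$labels)
    m
  })
  structure(list(order = order, coefficients = coefs,
                 intercepts = beta[1L, ], residual_covariance = Sigma,
                 aic = aic, n_eff = n_eff, residuals = res,
                 labels = series$labels),
            class = "mvar_model")
}

#' @export
print.mvar_model <- function(x, ...) {
  cat(sprintf("<mvar_model> order %d, %d processes, AIC = %.4g\n",
              x$order, length(x$labels), x$aic))
  invisible(x)
}

#' Select MVAR order by AIC
#'
#' Fits orders `1..max_order` on a common sample span and returns the AIC
#' minimizer (ties toward the smaller order).
#'
#' @inheritParams fit_mvar
#' @param max_order largest candidate order.
#' @return Integer order.
#' @export
select_order_aic <- function(series, max_order = 5L) {
  max_order <- as.integer(max_order)
  if (max_order < 1L) stop("max_order must be >= 1")
  n <- n_processes(series)
  aics <- vapply(seq_len(max_order), function(p) {
    d <- mvar_design(series$values, p, start = max_order + 1L)
    res <- qr.resid(qr(d$X), d$Y)  # pivoted QR: projection valid at any rank
    n_eff <- nrow(d$Y)
    Sigma <- crossprod(res) / n_eff
    # pseudo-determinant: rank-deficient channels (e.g. average-referenced
    # EEG) contribute zero eigenvalues that carry no information
    ev <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE, only.values = TRUE)$values
    ev <- ev[ev > max(ev) * 1e-10]
    if (!length(ev)) return(Inf)
    n_eff * sum(log(ev)) + 2 * p * n^2
  }, numeric(1))
  which.min(aics)  # which.min takes the first (smallest) index on ties
}

#' Granger-causality network (conditional MVAR)
#'
#' Model order is chosen by [select_order_aic()]. For each ordered pair
#' `(i, j)` the full model regresses `j`'s present on all processes' lags and
#' the restricted model omits `i`'s lags; the edge weight is
#' `log(sigma2_restricted / sigma2_full)` and significance comes from the
#' nested-model F-test at `params$alpha`.
#'
#' @inheritParams infer_bvte_network
#' @return A [directed_network()] with `method = "gca"` and attribute-free
#'   weights in log variance-ratio units.
#' @export
infer_gca_network <- function(series, params = inference_params()) {
  n <- n_processes(series)
  if (n < 2L) stop("need at least 2 processes to infer a network")
  p <- select_order_aic(series, params$max_order)
  d <- mvar_design(series$values, p)
  n_eff <- nrow(d$Y)
  if (n_eff - ncol(d$X) < 1L) stop("series too short for GCA at order ", p)
  lag_cols <- function(chans) {  # design columns of the given channels' lags
    c(1L, as.vector(outer(chans, n * (seq_len(p) - 1L), `+`)) + 1L)
  }
  qr_full <- qr(d$X)
  reduced <- qr_full$rank < ncol(d$X)
  if (reduced && n < 3L) stop("singular MVAR fit: rank-deficient regressor matrix")
  W <- matrix(0, n, n); B <- matrix(0L, n, n)
  rss_of <- function(cols, j) {
    q <- qr(d$X[, cols, drop = FALSE])
    sum(qr.resid(q, d$Y[, j])^2)
  }
  if (!reduced) {
    res_full <- qr.resid(qr_full, d$Y)
    rss_full <- colSums(res_full^2)
    df2 <- n_eff - ncol(d$X)
    for (i in seq_len(n)) {
      cols_r <- lag_cols(setdiff(seq_len(n), i))
      Xr <- d$X[, cols_r, drop = FALSE]
      rss_r <- colSums(qr.resid(qr(Xr), d$Y)^2)
      for (j in seq_len(n)) {
        if (i == j) next
        W[i, j] <- log(rss_r[j] / rss_full[j])
        Fstat <- ((rss_r[j] - rss_full[j]) / p) / (rss_full[j] / df2)
        B[i, j] <- as.integer(
          stats::pf(Fstat, p, df2, lower.tail = FALSE) <= params$alpha)
      }
    }
  } else {
    # exact collinearity across channels (e.g. average-referenced EEG):
    # leave-one-out conditioning — for each ordered pair, one fixed channel
    # outside the pair is dropped from the conditioning set so the source's
    # lags regain a unique contribution
    df2 <- n_eff - (1L + (n - 1L) * p)
    if (df2 < 1L) stop("series too short for GCA at order ", p)
    rss_cache <- new.env(parent = emptyenv())
    rss_all <- function(chans) {  # RSS per target for a given channel set
      key <- paste(chans, collapse = ",")
      if (is.null(rss_cache[[key]])) {
        q <- qr(d$X[, lag_cols(chans), drop = FALSE])
        rss_cache[[key]] <- colSums(qr.resid(q, d$Y)^2)
      }
      rss_cache[[key]]
    }
    for (j in seq_len(n)) {
      for (i in seq_len(n)) {
        if (i == j) next
        r0 <- max(setdiff(seq_len(n), c(i, j)))
        full_ch <- setdiff(seq_len(n), r0)
        rss_f <- rss_all(full_ch)[j]
        rss_r <- rss_all(setdiff(full_ch, i))[j]
        W[i, j] <- log(rss_r / rss_f)
        Fstat <- ((rss_r - rss_f) / p) / (rss_f / df2)
        B[i, j] <- as.integer(
          stats::pf(Fstat, p, df2, lower.tail = FALSE) <= params$alpha)
      }
    }
  }
  net <- directed_network(W, B, series$labels, "gca", params$alpha)
  net$order <- p
  net
}
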