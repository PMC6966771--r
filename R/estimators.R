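#' Embedding specification
#'
#' Finite uniform embedding used to approximate the (in principle infinite)
#' past histories entering the transfer-entropy definitions: `k_target` past
#' samples of the target, `l_source` past samples of each source/conditioning
#' process, successive past samples `delay` steps apart.
#'
#' @param k_target history length of the target process (>= 1).
#' @param l_source history length of each source/conditioning process (>= 1).
#' @param delay lag step, in samples, between successive past samples (>= 1).
#' @return An `embedding_spec` object.
#' @export
embedding_spec <- function(k_target = 1L, l_source = 1L, delay = 1L) {
  k_target <- as.integer(k_target); l_source <- as.integer(l_source)
  delay <- as.integer(delay)
  if (k_target < 1L || l_source < 1L || delay < 1L) {
    stop("k_target, l_source and delay must all be >= 1")
  }
  structure(list(k_target = k_target, l_source = l_source, delay = delay),
            class = "embedding_spec")
}

#' Discretize a multichannel series into symbols
#'
#' Per-process mapping of amplitudes to integer symbols in `[0, n_bins)`,
#' used by the plug-in probability estimator.
#'
#' @param series a [multichannel_series()].
#' @param n_bins number of symbols per process (>= 1).
#' @param scheme `"quantile"` (default; near-equal bin occupancy for
#'   continuous data) or `"equal_width"`.
#' @return Integer matrix of the same shape as `series$values`.
#' @export
discretize <- function(series, n_bins = 3L, scheme = c("quantile", "equal_width")) {
  scheme <- match.arg(scheme)
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) stop("n_bins must be >= 1")
  v <- series$values
  out <- matrix(0L, nrow(v), ncol(v), dimnames = dimnames(v))
  if (n_bins == 1L) return(out)
  for (i in seq_len(nrow(v))) {
    x <- v[i, ]
    rng <- range(x)
    if (rng[1] == rng[2]) {
      if (scheme == "quantile") {
        stop("process '", series$labels[i],
             "' is constant: quantile bins are degenerate for n_bins > 1")
      }
      next  # equal_width: all symbols 0
    }
    if (scheme == "equal_width") {
      br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
      sym <- findInterval(x, br[-c(1L, length(br))], left.open = FALSE)
    } else {
      # rank-based quantile bins: near-equal occupancy for continuous data,
      # ties always land in the same bin
      r <- rank(x, ties.method = "average")
      sym <- pmin(ceiling(r * n_bins / length(x)), n_bins) - 1L
    }
    out[i, ] <- as.integer(sym)
  }
  out
}

#' Time-delay embed a series
#'
#' Builds the aligned sample table of target present values and per-role past
#' vectors. Row `t` holds the target's present `x_t`, the target past
#' `(x_{t-delay}, ..., x_{t-k*delay})` and the analogous pasts of each source
#' and conditioning process; rows never straddle the start of the series.
#'
#' @param series a [multichannel_series()].
#' @param spec an [embedding_spec()].
#' @param target,sources,conditions processes by label or index.
#' @return List with `present` (numeric vector), `target_past`,
#'   `source_past`, `condition_past` (matrices, possibly 0-column) and
#'   `time_index` (1-based sample index of each present value).
#' @export
embed_series <- function(series, spec, target, sources = NULL, conditions = NULL) {
  tgt <- process_index(series, target, "target")
  src <- if (length(sources)) process_index(series, sources, "source") else integer(0)
  cnd <- if (length(conditions)) process_index(series, conditions, "condition") else integer(0)
  Tn <- n_samples(series)
  span <- max(spec$k_target, if (length(c(src, cnd))) spec$l_source else 0L) * spec$delay
  span <- max(span, spec$k_target * spec$delay)
  if (Tn <= span) {
    stop("series too short (", Tn, " samples) for embedding span ", span)
  }
  pres <- (span + 1L):Tn
  v <- series$values
  past <- function(p, depth) {
    m <- matrix(0, length(pres), depth)
    for (j in seq_len(depth)) m[, j] <- v[p, pres - j * spec$delay]
    m
  }
  tp <- past(tgt, spec$k_target)
  colnames(tp) <- paste0("tgt_lag", seq_len(spec$k_target))
  sp <- do.call(cbind, c(list(matrix(0, length(pres), 0L)),
                         lapply(src, past, depth = spec$l_source)))
  cp <- do.call(cbind, c(list(matrix(0, length(pres), 0L)),
                         lapply(cnd, past, depth = spec$l_source)))
  list(present = v[tgt, pres], target_past = tp, source_past = sp,
       condition_past = cp, time_index = pres)
}

# Surrogate shift offsets: uniform in [n/8, 7n/8], drawn without replacement
# per source whenever the range allows (duplicate rotations waste null
# resolution and make the test anti-conservative).
draw_offsets <- function(n_samples, n_perm, n_src, seed) {
  lo <- max(1L, as.integer(ceiling(n_samples / 8)))
  hi <- max(lo, as.integer(floor(7 * n_samples / 8)))
  rng <- hi - lo + 1L
  with_seed(seed, {
    m <- matrix(0L, n_perm, max(n_src, 1L))
    for (s in seq_len(max(n_src, 1L))) {
      m[, s] <- sample.int(rng, n_perm, replace = rng < n_perm) + lo - 1L
    }
    m
  })
}

# ---- internal plug-in machinery -------------------------------------------

# Shannon entropy (bits) of a vector of numeric codes. Small code ranges go
# through tabulate() (O(n)); large joint spaces fall back to sorting.
ent_codes <- function(codes, range = Inf) {
  n <- length(codes)
  if (range <= 4e6) {
    cnt <- tabulate(as.integer(codes) + 1L, nbins = as.integer(range))
    cnt <- cnt[cnt > 0L]
  } else {
    o <- sort.int(codes, method = "radix")
    brk <- c(which(o[-1L] != o[-n]), n)
    cnt <- diff(c(0L, brk))
  }
  p <- cnt / n
  -sum(p * log2(p))
}

# Encode columns of an integer matrix (0-based symbols) into joint codes.
enc_cols <- function(mat, n_bins) {
  if (ncol(mat) == 0L) return(numeric(nrow(mat)))
  code <- numeric(nrow(mat))
  for (j in seq_len(ncol(mat))) code <- code * n_bins + mat[, j]
  code
}

# Core conditional transfer entropy on pre-discretized symbols (plug-in) or
# raw values (gaussian). `shift` circularly shifts each source row (surrogate
# generation); discretization commutes with circular shifts so symbols are
# reused across surrogates.
te_core <- function(values, tgt, src, cnd, spec, estimator, n_bins,
                    shift = NULL, warn_dims = TRUE) {
  Tn <- ncol(values)
  if (!is.null(shift) && length(shift)) {
    for (i in seq_along(src)) {
      s <- shift[i] %% Tn
      if (s != 0L) {
        row <- values[src[i], ]
        values[src[i], ] <- c(row[(s + 1L):Tn], row[1L:s])
      }
    }
  }
  k <- spec$k_target; l <- spec$l_source; d <- spec$delay
  span <- max(k, l) * d
  if (Tn <= span) stop("series too short (", Tn, ") for embedding span ", span)
  pres <- (span + 1L):Tn
  n_eff <- length(pres)
  dims <- 1L + k + l * length(src) + l * length(cnd)
  if (estimator == "plugin") {
    grab <- function(p, depth) {
      m <- matrix(0L, n_eff, depth)
      for (j in seq_len(depth)) m[, j] <- values[p, pres - j * d]
      m
    }
    A <- do.call(cbind, c(list(grab(tgt, k)), lapply(cnd, grab, depth = l)))
    S <- do.call(cbind, c(list(matrix(0L, n_eff, 0L)), lapply(src, grab, depth = l)))
    present <- values[tgt, pres]
    if (warn_dims && n_bins^dims > n_eff) {
      warning("plug-in joint space (", n_bins, "^", dims,
              " cells) exceeds n_effective = ", n_eff,
              "; estimates may be strongly biased", call. = FALSE)
    }
    code_a <- enc_cols(A, n_bins)
    code_c <- code_a * n_bins^ncol(S) + enc_cols(S, n_bins)
    code_b <- code_a * n_bins + present
    code_d <- code_c * n_bins + present
    ra <- n_bins^ncol(A); rc <- ra * n_bins^ncol(S)
    h2 <- ent_codes(code_b, ra * n_bins) - ent_codes(code_a, ra)
    h1 <- ent_codes(code_d, rc * n_bins) - ent_codes(code_c, rc)
  } else {
    if (n_eff < 10L * dims) {
      stop("too few effective samples (", n_eff, ") for a gaussian fit in ",
           dims, " embedded dimensions (need >= ", 10L * dims, ")")
    }
    grab <- function(p, depth) {
      m <- matrix(0, n_eff, depth)
      for (j in seq_len(depth)) m[, j] <- values[p, pres - j * d]
      m
    }
    y <- values[tgt, pres]
    X1 <- do.call(cbind, c(list(rep(1, n_eff), grab(tgt, k)),
                           lapply(cnd, grab, depth = l)))
    X2 <- do.call(cbind, c(list(X1), lapply(src, grab, depth = l)))
    v1 <- sum(stats::.lm.fit(X1, y)$residuals^2) / n_eff
    v2 <- sum(stats::.lm.fit(X2, y)$residuals^2) / n_eff
    v1 <- max(v1, .Machine$double.eps); v2 <- max(v2, .Machine$double.eps)
    cc <- 0.5 * log2(2 * pi * exp(1))
    h2 <- cc + 0.5 * log2(v1)
    h1 <- cc + 0.5 * log2(v2)
  }
  structure(list(h1 = h1, h2 = h2, te = h2 - h1, estimator = estimator,
                 n_effective = n_eff), class = "te_computation")
}

#' @export
print.te_computation <- function(x, ...) {
  cat(sprintf("<te_computation> TE = %.6g bits (%s, n_eff = %d)\n",
              x$te, x$estimator, x$n_effective))
  invisible(x)
}

te_inputs <- function(series, source, target, conditions, estimator, n_bins) {
  src <- process_index(series, source, "source")
  tgt <- process_index(series, target, "target")
  cnd <- if (length(conditions)) process_index(series, conditions, "condition") else integer(0)
  if (any(src == tgt)) stop("source and target must differ")
  if (tgt %in% cnd) stop("target must not appear in the condition set")
  if (any(src %in% cnd)) stop("source must not appear in the condition set")
  if (estimator == "plugin" && n_bins < 2L) stop("plugin estimator needs n_bins >= 2")
  list(src = src, tgt = tgt, cnd = cnd)
}

#' Transfer entropy between two processes
#'
#' Information transferred from the source's past to the target's present
#' beyond the target's own past, in bits. The plug-in path evaluates the
#' discrete sum over observed symbol configurations with base-2 logarithms;
#' the gaussian path computes `0.5 * log2` of the ratio of least-squares
#' residual variances of the target's present given its own past versus given
#' its own and the source's past (the linear-Gaussian closed form, equal to
#' the Granger log-variance ratio divided by `2*ln 2`).
#'
#' @inheritParams embed_series
#' @param source,target processes by label or index (must differ).
#' @param estimator `"plugin"` (histogram) or `"gaussian"` (parametric).
#' @param n_bins symbols per process for the plug-in estimator (>= 2).
#' @return A `te_computation` with entropy rates `h1`, `h2`, their difference
#'   `te` (bits; may be slightly negative from finite samples) and
#'   `n_effective`.
#' @export
transfer_entropy <- function(series, source, target, spec = embedding_spec(),
                             estimator = c("plugin", "gaussian"), n_bins = 3L) {
  estimator <- match.arg(estimator)
  conditional_transfer_entropy(series, source, target, conditions = NULL,
                               spec = spec, estimator = estimator,
                               n_bins = n_bins)
}

#' Conditional (multivariate) transfer entropy
#'
#' Transfer entropy from `source` to `target` with the pasts of every process
#' in `conditions` added to both conditioning sets, so that information
#' already carried by the conditioning processes does not count. An empty
#' condition set reduces exactly to [transfer_entropy()].
#'
#' @inheritParams transfer_entropy
#' @param conditions processes (labels or indices) to condition on; must not
#'   contain `source` or `target`. `NULL` or empty for plain TE.
#' @return A `te_computation`.
#' @export
conditional_transfer_entropy <- function(series, source, target,
                                         conditions = NULL,
                                         spec = embedding_spec(),
                                         estimator = c("plugin", "gaussian"),
                                         n_bins = 3L) {
  estimator <- match.arg(estimator)
  n_bins <- as.integer(n_bins)
  ii <- te_inputs(series, source, target, conditions, estimator, n_bins)
  vals <- if (estimator == "plugin") discretize(series, n_bins) else series$values
  te_core(vals, ii$tgt, ii$src, ii$cnd, spec, estimator, n_bins)
}

#' Circular-shift surrogate significance test
#'
#' Tests a directed (conditional) transfer-entropy statistic against a null
#' in which the source is circularly shifted by a uniform random offset in
#' `[n/8, 7n/8]` samples — preserving its autocorrelation while destroying
#' any cross-coupling. The p-value uses the permutation `+1` correction:
#' `p = (1 + #{surrogate >= observed}) / (1 + n_perm)`.
#'
#' @inheritParams conditional_transfer_entropy
#' @param n_perm number of surrogates (>= 19 so that alpha = 0.05 is
#'   attainable).
#' @param alpha significance level in (0, 1).
#' @param seed integer seed; fixed seed gives identical results.
#' @param statistic optional custom statistic
#'   `function(series, source, target, conditions) -> numeric`; the default
#'   uses the package estimator with a fast symbol-shift path.
#' @return A `surrogate_result` with `observed`, `surrogate_values`,
#'   `p_value`, `n_perm`, `alpha` and `significant`.
#' @export
surrogate_test <- function(series, source, target, conditions = NULL,
                           spec = embedding_spec(),
                           estimator = c("plugin", "gaussian"), n_bins = 3L,
                           n_perm = 199L, alpha = 0.05, seed = NULL,
                           statistic = NULL) {
  estimator <- match.arg(estimator)
  n_perm <- as.integer(n_perm)
  if (n_perm < 19L) stop("n_perm must be >= 19 to resolve alpha = 0.05")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  n_bins <- as.integer(n_bins)
  ii <- te_inputs(series, source, target, conditions, estimator, n_bins)
  Tn <- n_samples(series)
  offs <- draw_offsets(Tn, n_perm, length(ii$src),
                       if (is.null(seed)) NULL else derive_seed(seed, ii$tgt, "offsets"))
  use_fast <- is.null(statistic)
  if (use_fast) {
    vals <- if (estimator == "plugin") discretize(series, n_bins) else series$values
    obs <- suppressWarnings(
      te_core(vals, ii$tgt, ii$src, ii$cnd, spec, estimator, n_bins)$te)
  } else {
    obs <- statistic(series, source, target, conditions)
  }
  surr <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    off <- offs[b, ]
    if (use_fast) {
      surr[b] <- suppressWarnings(
        te_core(vals, ii$tgt, ii$src, ii$cnd, spec, estimator, n_bins,
                shift = off)$te)
    } else {
      sh <- series
      for (i in seq_along(ii$src)) {
        row <- sh$values[ii$src[i], ]
        s <- off[i] %% Tn
        if (s) sh$values[ii$src[i], ] <- c(row[(s + 1L):Tn], row[1L:s])
      }
      surr[b] <- statistic(sh, source, target, conditions)
    }
  }
  p <- (1 + sum(surr >= obs)) / (1 + n_perm)
  structure(list(observed = obs, surrogate_values = surr, p_value = p,
                 n_perm = n_perm, alpha = alpha, significant = p <= alpha),
            class = "surrogate_result")
}

#' @export
print.surrogate_result <- function(x, ...) {
  cat(sprintf("<surrogate_result> observed = %.5g, p = %.4g (%d surrogates)%s\n",
              x$observed, x$p_value, x$n_perm,
              if (x$significant) " *" else ""))
  invisible(x)
}
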