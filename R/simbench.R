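#' Ground-truth directed network
#'
#' Binary adjacency (row = source) of a predefined simulation topology. The
#' canonical topologies mix unidirectional and bidirectional couplings and
#' give every node at least one edge.
#'
#' @param adjacency square 0/1 matrix with zero diagonal.
#' @param name topology identifier.
#' @return A `ground_truth_network`.
#' @export
ground_truth_network <- function(adjacency, name = "custom") {
  adjacency <- as.matrix(adjacency)
  n <- nrow(adjacency)
  if (ncol(adjacency) != n) stop("adjacency must be square")
  if (any(diag(adjacency) != 0)) stop("adjacency diagonal must be zero")
  adjacency <- (adjacency != 0) * 1L
  if (is.null(rownames(adjacency))) {
    dimnames(adjacency) <- list(paste0("N", seq_len(n)), paste0("N", seq_len(n)))
  }
  structure(list(adjacency = adjacency, n = n, name = name,
                 labels = rownames(adjacency)),
            class = "ground_truth_network")
}

#' @export
print.ground_truth_network <- function(x, ...) {
  cat(sprintf("<ground_truth_network> '%s': %d nodes, %d edges, %d ordered-pair slots\n",
              x$name, x$n, sum(x$adjacency), x$n * (x$n - 1L)))
  invisible(x)
}

edge_df_to_adj <- function(edges, labels) {
  A <- matrix(0L, length(labels), length(labels),
              dimnames = list(labels, labels))
  for (r in seq_len(nrow(edges))) A[edges[r, 1L], edges[r, 2L]] <- 1L
  A
}

#' Built-in simulation topologies
#'
#' `sim8`: 8 nodes, 12 directed edges (one bidirectional pair 4<->5, ten
#' unidirectional), 56 ordered-pair linkage slots. `sim7`: 7 nodes, 10
#' directed edges (one bidirectional pair 3<->4), 42 slots. Every node has
#' degree >= 1.
#'
#' @param name `"sim8"` or `"sim7"`.
#' @return A [ground_truth_network()].
#' @export
builtin_topology <- function(name) {
  edges <- switch(name,
    sim8 = rbind(c(1L, 2L), c(1L, 3L), c(2L, 4L), c(3L, 4L), c(2L, 7L),
                 c(3L, 6L), c(4L, 5L), c(5L, 4L), c(5L, 6L), c(5L, 7L),
                 c(6L, 8L), c(7L, 8L)),
    sim7 = rbind(c(1L, 2L), c(1L, 3L), c(2L, 4L), c(2L, 6L), c(3L, 7L),
                 c(3L, 4L), c(4L, 3L), c(4L, 5L), c(5L, 6L), c(6L, 7L)),
    stop("unknown topology '", name, "'; valid names: sim8, sim7"))
  n <- if (name == "sim8") 8L else 7L
  ground_truth_network(edge_df_to_adj(edges, paste0("N", seq_len(n))), name)
}

#' Coupling specification
#'
#' Names the causal-relationship function and the distribution of the edge
#' strengths. Available functions: `linear` (`Y = A x B`),
#' `C` (`cos(x) + sin(x)`), `f` (`21.6 x / (1 + exp(-4x))`, reading the
#' printed "2.40 x 9x" literally; `f_mode = "compact"` selects `2.409 x`
#' instead), `cosinusoidal` (`cos(2*pi*x)`), `H` (`exp(sin(2*pi*x))`) and
#' `S` (the logistic `1 / (1 + exp(-x))`).
#'
#' @param fun coupling function name.
#' @param coefficient_range interval within (0, 1) the edge strengths are
#'   drawn from (uniformly, once per run).
#' @param innovation_sd standard deviation of the Gaussian innovations.
#' @param f_mode `"literal"` or `"compact"` reading of the `f` numerator.
#' @return A `coupling_spec`.
#' @export
coupling_spec <- function(fun = c("linear", "C", "f", "cosinusoidal", "H", "S"),
                          coefficient_range = c(0.3, 0.6),
                          innovation_sd = 1, f_mode = c("literal", "compact")) {
  fun <- match.arg(fun)
  f_mode <- match.arg(f_mode)
  if (length(coefficient_range) != 2L || any(coefficient_range <= 0) ||
      any(coefficient_range >= 1) || diff(coefficient_range) < 0) {
    stop("coefficient_range must be an interval within (0, 1)")
  }
  if (innovation_sd <= 0) stop("innovation_sd must be positive")
  structure(list(fun = fun, coefficient_range = coefficient_range,
                 innovation_sd = innovation_sd, f_mode = f_mode),
            class = "coupling_spec")
}

#' Evaluate a coupling nonlinearity
#'
#' Exact evaluation of the printed causal-relationship functions.
#'
#' @param fun function name (see [coupling_spec()]).
#' @param x numeric input.
#' @param f_mode `"literal"` (`21.6 x`) or `"compact"` (`2.409 x`) numerator
#'   of `f`.
#' @return Numeric of the same length as `x`.
#' @export
apply_nonlinearity <- function(fun, x, f_mode = c("literal", "compact")) {
  f_mode <- match.arg(f_mode)
  switch(fun,
         linear = x,
         C = cos(x) + sin(x),
         f = (if (f_mode == "literal") 21.6 else 2.409) * x / (1 + exp(-4 * x)),
         cosinusoidal = cos(2 * pi * x),
         H = exp(sin(2 * pi * x)),
         S = 1 / (1 + exp(-x)),
         stop("unknown coupling function '", fun,
              "'; valid: linear, C, f, cosinusoidal, H, S"))
}

# Moments of r(Z), Z ~ N(0,1), by deterministic quadrature: mean, sd and the
# linearized gain E[Z * r~(Z)] used for stability rescaling.
nonlin_moments <- function(fun, f_mode = "literal") {
  z <- seq(-8, 8, by = 0.002)
  w <- stats::dnorm(z); w <- w / sum(w)
  r <- apply_nonlinearity(fun, z, f_mode)
  mu <- sum(w * r)
  sd <- sqrt(max(sum(w * (r - mu)^2), .Machine$double.eps))
  gain <- sum(w * z * (r - mu)) / sd
  list(mu = mu, sd = sd, gain = gain)
}

#' Generate coupled time series from a ground-truth network
#'
#' Linear systems follow
#' `x_j(t) = sum_i a_ij x_i(t-1) + 0.3 x_j(t-1) + e_j(t)`; non-linear systems
#' replace `x_i(t-1)` by the standardized coupling function
#' `r~(x_i(t-1))` (zero mean, unit variance under standard-normal input).
#' Edge coefficients are drawn once per run from `coefficient_range` and the
#' coefficient matrix is rescaled so the linearized system has spectral
#' radius <= 0.9; a 200-sample burn-in is discarded and non-linear output
#' channels are standardized. Deterministic under `seed`.
#'
#' @param gt a [ground_truth_network()].
#' @param coupling a [coupling_spec()].
#' @param n_obs samples returned per channel (>= 100).
#' @param seed integer seed.
#' @param burn_in samples discarded before the returned window.
#' @return List with `series` (a [multichannel_series()]) and `coefficients`
#'   (the realized edge-strength matrix, row = source).
#' @export
generate_series <- function(gt, coupling, n_obs = 500L, seed = 1L,
                            burn_in = 200L) {
  stopifnot(inherits(gt, "ground_truth_network"),
            inherits(coupling, "coupling_spec"))
  n_obs <- as.integer(n_obs)
  if (n_obs < 100L) stop("n_obs must be >= 100")
  n <- gt$n
  mom <- nonlin_moments(coupling$fun, coupling$f_mode)
  with_seed(seed, {
    A <- matrix(0, n, n)
    ne <- sum(gt$adjacency)
    A[gt$adjacency == 1L] <- stats::runif(ne, coupling$coefficient_range[1],
                                          coupling$coefficient_range[2])
    # rescale so the linearization (gain * A + 0.3 I) has spectral radius <= 0.9
    ev <- eigen(A, only.values = TRUE)$values
    sr <- function(s) max(Mod(0.3 + abs(mom$gain) * s * ev))
    s <- 1
    if (length(ev) && sr(1) > 0.9) {
      lohi <- c(0, 1)
      for (it in 1:40) {
        mid <- mean(lohi)
        if (sr(mid) > 0.9) lohi[2] <- mid else lohi[1] <- mid
      }
      s <- lohi[1]
    }
    A <- A * s
    At <- t(A)  # dynamics operate target-major
    Tn <- n_obs + burn_in
    eps <- matrix(stats::rnorm(n * Tn, sd = coupling$innovation_sd), n, Tn)
    x <- matrix(0, n, Tn)
    x[, 1L] <- eps[, 1L]
    if (coupling$fun == "linear") {
      for (t in 2:Tn) x[, t] <- At %*% x[, t - 1L] + 0.3 * x[, t - 1L] + eps[, t]
    } else {
      for (t in 2:Tn) {
        r <- (apply_nonlinearity(coupling$fun, x[, t - 1L], coupling$f_mode) -
                mom$mu) / mom$sd
        x[, t] <- At %*% r + 0.3 * x[, t - 1L] + eps[, t]
      }
    }
    if (!all(is.finite(x))) {
      stop("generation error: system diverged (non-finite values) for coupling '",
           coupling$fun, "'")
    }
    x <- x[, (burn_in + 1L):Tn, drop = FALSE]
    if (coupling$fun != "linear") {
      x <- t(scale(t(x)))  # standardize each output channel
    }
    dimnames(A) <- list(gt$labels, gt$labels)
    list(series = multichannel_series(x, gt$labels), coefficients = A)
  })
}

#' Add channel-wise Gaussian noise at a target SNR
#'
#' Per channel, adds iid Gaussian noise with standard deviation
#' `sd(signal) * 10^(-snr_db / 20)`, i.e. SNR defined as
#' `10 * log10(P_signal / P_noise)` in dB.
#'
#' @param series a [multichannel_series()].
#' @param snr_db target signal-to-noise ratio in dB (finite).
#' @param seed integer seed.
#' @return A noise-contaminated [multichannel_series()].
#' @export
add_noise <- function(series, snr_db, seed = 1L) {
  if (!is.finite(snr_db)) stop("snr_db must be finite")
  v <- series$values
  with_seed(seed, {
    for (i in seq_len(nrow(v))) {
      sd_n <- stats::sd(v[i, ]) * 10^(-snr_db / 20)
      v[i, ] <- v[i, ] + stats::rnorm(ncol(v), sd = sd_n)
    }
    multichannel_series(v, series$labels, series$sample_rate)
  })
}

#' Simulation-benchmark configuration
#'
#' @param topology `"sim8"` or `"sim7"` (or a [ground_truth_network()]).
#' @param coupling a [coupling_spec()].
#' @param n_obs observations per channel (default 500).
#' @param snr_db_levels SNR levels in dB (default `c(-10, -5, 5, 10)`).
#' @param n_runs repetitions with fresh noise realizations (default 200).
#' @param methods subset of `c("gca", "bvte", "mte")`.
#' @param seed root seed.
#' @return A `simulation_config`.
#' @export
simulation_config <- function(topology = "sim8",
                              coupling = coupling_spec("linear"),
                              n_obs = 500L,
                              snr_db_levels = c(-10, -5, 5, 10),
                              n_runs = 200L,
                              methods = c("gca", "bvte", "mte"),
                              seed = 1L) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (n_obs < 100L) stop("n_obs must be >= 100")
  if (n_runs < 1L) stop("n_runs must be >= 1")
  gt <- if (inherits(topology, "ground_truth_network")) topology else
    builtin_topology(topology)
  structure(list(topology = gt, coupling = coupling, n_obs = as.integer(n_obs),
                 snr_db_levels = snr_db_levels, n_runs = as.integer(n_runs),
                 methods = methods, seed = seed),
            class = "simulation_config")
}

infer_by_method <- function(series, method, params) {
  switch(method,
         gca = infer_gca_network(series, params),
         bvte = infer_bvte_network(series, params),
         mte = infer_mte_network(series, params),
         stop("unknown method '", method, "'"))
}

#' Run the simulation benchmark
#'
#' For every run, generates a fresh realization of the configured system,
#' infers each method's network on the clean series (providing the noise-free
#' reference of the adjacency-bias measure), then for every SNR level
#' contaminates the series, re-infers, and scores against the ground truth.
#' A failing record is logged and skipped, never aborting the sweep; the full
#' sweep is deterministic under the config seed.
#'
#' @param config a [simulation_config()].
#' @param params an [inference_params()] shared by all methods (its seed is
#'   re-derived per run from the config seed).
#' @return Data frame with one row per (run, SNR, method): `topology`,
#'   `coupling`, `snr_db`, `run`, `method`, `bias`, `edges_recovered`,
#'   `sensitivity`, `specificity`.
#' @export
run_benchmark <- function(config, params = inference_params(n_perm = 19L)) {
  gt <- config$topology
  rows <- list()
  for (r in seq_len(config$n_runs)) {
    run_seed <- derive_seed(config$seed, "run", r)
    gen <- generate_series(gt, config$coupling, config$n_obs, seed = run_seed)
    clean <- gen$series
    nets_clean <- list()
    for (m in config$methods) {
      pm <- params; pm$seed <- derive_seed(run_seed, m, "clean")
      nets_clean[[m]] <- tryCatch(
        suppressWarnings(infer_by_method(clean, m, pm)),
        error = function(e) {
          log_msg("run ", r, " clean ", m, " failed: ", conditionMessage(e))
          NULL
        })
    }
    for (snr in config$snr_db_levels) {
      noisy <- add_noise(clean, snr, seed = derive_seed(run_seed, "noise", round(snr * 10)))
      for (m in config$methods) {
        if (is.null(nets_clean[[m]])) next
        pm <- params; pm$seed <- derive_seed(run_seed, m, round(snr * 10))
        net <- tryCatch(
          suppressWarnings(infer_by_method(noisy, m, pm)),
          error = function(e) {
            log_msg("run ", r, " snr ", snr, " ", m, " failed: ",
                    conditionMessage(e))
            NULL
          })
        if (is.null(net)) next
        cc <- confusion_counts(net, gt)
        rows[[length(rows) + 1L]] <- data.frame(
          topology = gt$name, coupling = config$coupling$fun, snr_db = snr,
          run = r, method = m,
          bias = adjacency_bias(nets_clean[[m]], net),
          edges_recovered = cc$tp + cc$tn,
          sensitivity = sensitivity(cc), specificity = specificity(cc))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
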