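#' Confusion counts between an estimated and a true directed network
#'
#' Compares presence/absence over all ordered off-diagonal node pairs:
#' TP = true edges detected, TN = absent edges correctly left out,
#' FP = absent edges flagged, FN = true edges missed. Counts always sum to
#' `n * (n - 1)`.
#'
#' @param estimated a [directed_network()] or a square binary matrix.
#' @param truth a ground-truth binary adjacency (matrix or
#'   `ground_truth_network`), same shape/labels.
#' @return List of class `confusion_counts` with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(estimated, truth) {
  est <- binary_of(estimated)
  tru <- binary_of(truth)
  if (!all(dim(est) == dim(tru))) stop("estimated and truth differ in shape")
  le <- rownames(est); lt <- rownames(tru)
  if (!is.null(le) && !is.null(lt) && !identical(le, lt)) {
    stop("estimated and truth differ in node labels")
  }
  off <- row(est) != col(est)
  e <- est[off] != 0; t_ <- tru[off] != 0
  structure(list(tp = sum(e & t_), tn = sum(!e & !t_),
                 fp = sum(e & !t_), fn = sum(!e & t_)),
            class = "confusion_counts")
}

binary_of <- function(x) {
  if (inherits(x, "directed_network")) return(x$binary)
  if (inherits(x, "ground_truth_network")) return(x$adjacency)
  m <- as.matrix(x)
  if (nrow(m) != ncol(m)) stop("adjacency must be square")
  m
}

#' Sensitivity and specificity (percent)
#'
#' `sensitivity = 100 * TP / (TP + FN)`; `specificity = 100 * TN / (TN + FP)`.
#' A zero denominator yields `NA` (an undefined-value marker excluded from
#' aggregation), not an error.
#'
#' @param counts a [confusion_counts()] result.
#' @return Percentage in `[0, 100]`, or `NA_real_`.
#' @export
sensitivity <- function(counts) {
  d <- counts$tp + counts$fn
  if (d == 0) return(NA_real_)
  100 * counts$tp / d
}

#' @rdname sensitivity
#' @export
specificity <- function(counts) {
  d <- counts$tn + counts$fp
  if (d == 0) return(NA_real_)
  100 * counts$tn / d
}

#' Adjacency-matrix linkage bias
#'
#' Normalized distance between the network estimated without added noise
#' (`y_c`) and its noise-contaminated counterpart (`y_b`):
#' `||y_c - y_b||_F / ||y_c||_F` (Frobenius norm, hence scale invariant).
#'
#' @param y_c,y_b weight matrices of the same shape.
#' @return Non-negative scalar; `NA_real_` when `||y_c|| = 0`.
#' @export
adjacency_bias <- function(y_c, y_b) {
  y_c <- weights_of(y_c); y_b <- weights_of(y_b)
  if (!all(dim(y_c) == dim(y_b))) stop("matrices differ in shape")
  nc <- sqrt(sum(y_c^2))
  if (nc == 0) return(NA_real_)
  sqrt(sum((y_c - y_b)^2)) / nc
}

weights_of <- function(x) {
  if (inherits(x, "directed_network")) x$weights else as.matrix(x)
}

#' Edges recovered
#'
#' Number of ordered off-diagonal pairs whose estimated presence/absence
#' agrees with the predefined network, i.e. `TP + TN` (perfect recovery of an
#' 8-node network scores 56).
#'
#' @inheritParams confusion_counts
#' @return Integer agreement count.
#' @export
edges_recovered <- function(estimated, truth) {
  cc <- confusion_counts(estimated, truth)
  cc$tp + cc$tn
}

#' Aggregate benchmark records and compare methods
#'
#' Produces the "mean ± sd" summary of each metric per
#' (coupling, SNR, method) cell — sample (n-1) standard deviation — and a
#' paired two-sided t-test across shared run indices for every method pair
#' within each (coupling, SNR, metric) cell. Identical per-run vectors are
#' reported as non-significant with `p = 1` by convention.
#'
#' @param records data frame of benchmark records as produced by
#'   [run_benchmark()] (columns `topology`, `coupling`, `snr_db`, `run`,
#'   `method`, `bias`, `edges_recovered`, `sensitivity`, `specificity`).
#' @param alpha significance level of the pairwise tests.
#' @return List with `summary` and `tests` data frames.
#' @export
aggregate_and_compare <- function(records, alpha = 0.05) {
  metrics <- c("bias", "edges_recovered", "sensitivity", "specificity")
  stopifnot(all(c("coupling", "snr_db", "run", "method", metrics) %in%
                  names(records)))
  key <- interaction(records$coupling, records$snr_db, records$method,
                     drop = TRUE)
  summ <- do.call(rbind, lapply(split(records, key), function(d) {
    out <- data.frame(coupling = d$coupling[1], snr_db = d$snr_db[1],
                      method = d$method[1], n_runs = nrow(d))
    for (m in metrics) {
      x <- d[[m]][!is.na(d[[m]])]
      out[[paste0(m, "_mean")]] <- mean(x)
      out[[paste0(m, "_sd")]] <- if (length(x) > 1L) stats::sd(x) else NA_real_
    }
    out
  }))
  rownames(summ) <- NULL

  tests <- list()
  cells <- split(records, interaction(records$coupling, records$snr_db,
                                      drop = TRUE))
  for (d in cells) {
    meths <- sort(unique(d$method))
    if (length(meths) < 2L) next
    for (a in seq_along(meths)) for (b in seq_along(meths)) {
      if (a >= b) next
      da <- d[d$method == meths[a], ]; db <- d[d$method == meths[b], ]
      runs <- intersect(da$run, db$run)
      if (!length(runs)) {
        stop("methods ", meths[a], " and ", meths[b],
             " share no run indices; cannot pair")
      }
      xa <- da[match(runs, da$run), ]; xb <- db[match(runs, db$run), ]
      for (m in metrics) {
        dd <- xa[[m]] - xb[[m]]
        dd <- dd[!is.na(dd)]
        if (length(dd) < 2L) next
        p <- if (all(dd == 0)) 1 else if (stats::sd(dd) == 0) 0 else
          stats::t.test(dd)$p.value
        tests[[length(tests) + 1L]] <- data.frame(
          coupling = d$coupling[1], snr_db = d$snr_db[1], metric = m,
          method_a = meths[a], method_b = meths[b],
          mean_diff = mean(dd), p_value = p, significant = p <= alpha)
      }
    }
  }
  tests <- if (length(tests)) do.call(rbind, tests) else
    data.frame(coupling = character(0), snr_db = numeric(0),
               metric = character(0), method_a = character(0),
               method_b = character(0), mean_diff = numeric(0),
               p_value = numeric(0), significant = logical(0))
  rownames(tests) <- NULL
  list(summary = summ, tests = tests)
}
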