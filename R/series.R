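#' Multichannel time series
#'
#' The basic container of the package: a `n_processes x n_samples` matrix of
#' real-valued amplitudes with unique per-process labels and an optional
#' sampling rate (absent for abstract simulations, Hz for EEG).
#'
#' @param values numeric matrix, one row per process, one column per sample.
#' @param labels character vector of unique process identifiers; defaults to
#'   `X1..Xn`.
#' @param sample_rate samples per second, or `NULL` for unitless series.
#' @return An object of class `multichannel_series` with elements `values`,
#'   `labels` and `sample_rate`.
#' @examples
#' s <- multichannel_series(matrix(rnorm(200), nrow = 2), labels = c("X", "Y"))
#' n_processes(s)
#' @export
multichannel_series <- function(values, labels = NULL, sample_rate = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L) stop("need at least one process")
  if (ncol(values) < 2L) stop("need at least two samples")
  if (!all(is.finite(values))) stop("series values must all be finite")
  if (is.null(labels)) labels <- paste0("X", seq_len(nrow(values)))
  labels <- as.character(labels)
  if (length(labels) != nrow(values)) {
    stop("labels must have length n_processes (", nrow(values), ")")
  }
  if (anyDuplicated(labels)) stop("process labels must be unique")
  if (!is.null(sample_rate)) {
    sample_rate <- as.numeric(sample_rate)
    if (!is.finite(sample_rate) || sample_rate <= 0) {
      stop("sample_rate must be a positive number")
    }
  }
  rownames(values) <- labels
  structure(list(values = values, labels = labels, sample_rate = sample_rate),
            class = "multichannel_series")
}

#' @export
print.multichannel_series <- function(x, ...) {
  cat(sprintf("<multichannel_series> %d processes x %d samples",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$sample_rate)) cat(sprintf(" @ %g Hz", x$sample_rate))
  cat("\n  processes: ", paste(utils::head(x$labels, 8L), collapse = ", "),
      if (length(x$labels) > 8L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @rdname multichannel_series
#' @param x object to query.
#' @export
n_processes <- function(x) nrow(x$values)

#' @rdname multichannel_series
#' @export
n_samples <- function(x) ncol(x$values)

# Resolve a process given as label or index to a validated integer index.
process_index <- function(series, p, arg = "process") {
  if (is.character(p)) {
    idx <- match(p, series$labels)
    if (anyNA(idx)) stop("unknown ", arg, ": ", paste(p[is.na(idx)], collapse = ", "))
    return(idx)
  }
  idx <- as.integer(p)
  if (any(idx < 1L | idx > n_processes(series))) {
    stop(arg, " index out of range 1..", n_processes(series))
  }
  idx
}
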