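# Internal helpers: deterministic seed fan-out and local RNG scopes.
#
# One root seed reproduces a whole experiment; every stochastic sub-step
# (surrogate index, benchmark run, subject) draws from a substream whose seed
# is a deterministic hash of the root seed and a key path. All derived seeds
# stay below 2^31 - 1 so they are valid R integers.

derive_seed <- function(seed, ...) {
  keys <- c(...)
  h <- as.double(seed %% 2147483647L)
  for (k in keys) {
    if (is.character(k)) k <- sum(utf8ToInt(k) * seq_along(utf8ToInt(k)))
    h <- (h * 48271 + as.double(k) + 1) %% 2147483647
  }
  as.integer(h %% 2147483646) + 1L
}

# Evaluate `expr` under a temporary RNG state seeded with `seed` (NULL leaves
# the global stream untouched).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

log_msg <- function(..., file = NULL) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  paste0(...))
  if (!is.null(file)) cat(line, "\n", file = file, append = TRUE, sep = "")
  message(line)
}
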