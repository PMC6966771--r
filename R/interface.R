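#' Read and write multichannel series as delimited text
#'
#' One row per process: the process label, a tab, then the sample values.
#' Comment lines starting with `#` may carry metadata (`# sample_rate: 1000`).
#' The round-trip is lossless to full double precision (`%.17g`).
#'
#' @param path file path.
#' @return [read_series()] returns a [multichannel_series()].
#' @export
read_series <- function(path) {
  lines <- readLines(path)
  sr <- NULL
  meta <- grep("^#", lines)
  for (m in meta) {
    mm <- regmatches(lines[m], regexec("sample_rate:\\s*([0-9.eE+-]+)", lines[m]))[[1]]
    if (length(mm) == 2L) sr <- as.numeric(mm[2])
  }
  body <- setdiff(seq_along(lines), meta)
  body <- body[nzchar(trimws(lines[body]))]
  if (!length(body)) stop("no data rows in ", path)
  parts <- strsplit(lines[body], "\t", fixed = TRUE)
  widths <- lengths(parts)
  if (length(unique(widths)) != 1L) {
    bad <- body[which(widths != widths[1])[1]]
    stop("parse error in ", path, ": ragged row at line ", bad)
  }
  labels <- vapply(parts, `[[`, character(1), 1L)
  vals <- t(vapply(parts, function(p) {
    x <- suppressWarnings(as.numeric(p[-1L]))
    x
  }, numeric(widths[1] - 1L)))
  if (anyNA(vals)) {
    bad <- body[which(rowSums(is.na(vals)) > 0)[1]]
    stop("parse error in ", path, ": non-numeric value at line ", bad)
  }
  multichannel_series(vals, labels, sr)
}

#' @rdname read_series
#' @param series a [multichannel_series()].
#' @export
write_series <- function(series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cat("# multichannel series: one row per process (label \\t samples)\n",
      file = con)
  if (!is.null(series$sample_rate)) {
    cat(sprintf("# sample_rate: %g\n", series$sample_rate), file = con)
  }
  for (i in seq_len(n_processes(series))) {
    cat(series$labels[i], sprintf("%.17g", series$values[i, ]), sep = "\t",
        file = con)
    cat("\n", file = con)
  }
  invisible(path)
}

#' Read and write directed networks
#'
#' Matrix form: a commented header recording method, alpha and the
#' row = source orientation, then two tab-separated labelled matrices
#' (weights, binary). [write_edge_list()] writes the long form
#' (source, target, weight, significant).
#'
#' @param path file path.
#' @return [read_network()] returns a [directed_network()].
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getmeta <- function(key, default = NA_character_) {
    m <- regmatches(hdr, regexec(paste0(key, ":\\s*(\\S+)"), hdr))
    hit <- Filter(function(x) length(x) == 2L, m)
    if (length(hit)) hit[[1]][2] else default
  }
  method <- getmeta("method")
  alpha <- suppressWarnings(as.numeric(getmeta("alpha")))
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  sec <- which(body == "> binary")
  wsec <- which(body == "> weights")
  if (!length(sec) || !length(wsec)) stop("malformed network file ", path)
  parse_mat <- function(txt) {
    cn <- strsplit(txt[1], "\t", fixed = TRUE)[[1]][-1L]
    rows <- strsplit(txt[-1L], "\t", fixed = TRUE)
    rn <- vapply(rows, `[[`, character(1), 1L)
    m <- t(vapply(rows, function(r) as.numeric(r[-1L]), numeric(length(cn))))
    dimnames(m) <- list(rn, cn)
    m
  }
  W <- parse_mat(body[(wsec + 1L):(sec - 1L)])
  B <- parse_mat(body[(sec + 1L):length(body)])
  directed_network(W, B, rownames(W), method, alpha)
}

#' @rdname read_network
#' @param network a [directed_network()].
#' @export
write_network <- function(network, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cat(sprintf("# directed network\n# method: %s\n# alpha: %s\n# orientation: row=source,col=target\n",
              network$method, format(network$alpha)), file = con)
  dump_mat <- function(m, tag, fmt) {
    cat("> ", tag, "\n", sep = "", file = con)
    cat("", colnames(m), sep = "\t", file = con); cat("\n", file = con)
    for (i in seq_len(nrow(m))) {
      cat(rownames(m)[i], sprintf(fmt, m[i, ]), sep = "\t", file = con)
      cat("\n", file = con)
    }
  }
  dump_mat(network$weights, "weights", "%.17g")
  dump_mat(network$binary, "binary", "%d")
  invisible(path)
}

#' @rdname read_network
#' @export
write_edge_list <- function(network, path) {
  n <- nrow(network$weights)
  idx <- which(row(network$weights) != col(network$weights))
  df <- data.frame(source = network$labels[row(network$weights)[idx]],
                   target = network$labels[col(network$weights)[idx]],
                   weight = network$weights[idx],
                   significant = network$binary[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- command-line interface ------------------------------------------------

cli_usage <- function() {
  cat("usage: mtenet <subcommand> [options]\n",
      "subcommands:\n",
      "  simulate-benchmark --out DIR [--config FILE] [--topology sim8]\n",
      "      [--coupling linear] [--runs N] [--n-obs N] [--snr a,b,...]\n",
      "      [--methods gca,bvte,mte] [--n-perm N] [--seed S]\n",
      "  synth-cohorts --out DIR [--hc N] [--scz M] [--runs R]\n",
      "      [--stimuli N] [--targets K] [--seed S]\n",
      "  infer-network --in FILE --out FILE [--method mte] [--alpha A]\n",
      "      [--n-perm N] [--estimator plugin] [--bins B] [--seed S]\n",
      "  compare-groups --hc-dir D1 --scz-dir D2 --out DIR [--method gca]\n",
      "      [--alpha A] [--seed S]\n",
      "  report --records FILE --out DIR [--alpha A]\n", sep = "")
}

parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      flags[[key]] <- TRUE; i <- i + 1L
    } else {
      flags[[key]] <- args[i + 1L]; i <- i + 2L
    }
  }
  flags
}

write_manifest <- function(dir, config) {
  config$package_version <- as.character(utils::packageVersion("mtenet"))
  config$r_version <- R.version.string
  jsonlite::write_json(config, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate-benchmark`, `synth-cohorts`,
#' `infer-network`, `compare-groups` and `report`; every run writes its
#' outputs, a manifest (config echo, seed, versions) and a log into the
#' output directory. Returns the exit status (0 success, 2 usage error)
#' instead of quitting, so it is scriptable and testable; see
#' `system.file("cli", "mtenet.R", package = "mtenet")` for the executable
#' wrapper.
#'
#' @param argv character vector of arguments (default: the command line).
#' @return Integer exit status, invisibly.
#' @export
run_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(argv)) { cli_usage(); return(invisible(2L)) }
    sub <- argv[1]
    flags <- parse_flags(argv[-1L])
    num <- function(key, default) as.numeric(flags[[key]] %||% default)
    int <- function(key, default) as.integer(num(key, default))
    chr <- function(key, default = NULL) {
      v <- flags[[key]]
      if (is.null(v)) default else as.character(v)
    }
    switch(sub,
      "simulate-benchmark" = {
        out <- chr("out"); if (is.null(out)) stop("--out is required")
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        logf <- file.path(out, "log.txt")
        cfgfile <- chr("config")
        cfg <- if (!is.null(cfgfile)) jsonlite::read_json(cfgfile) else list()
        seed <- int("seed", cfg$seed %||% 1L)
        snr <- as.numeric(strsplit(chr("snr", paste(
          unlist(cfg$snr_db_levels) %||% c(-10, -5, 5, 10), collapse = ",")),
          ",")[[1]])
        methods <- strsplit(chr("methods", paste(
          unlist(cfg$methods) %||% c("gca", "bvte", "mte"), collapse = ",")),
          ",")[[1]]
        config <- simulation_config(
          topology = chr("topology", cfg$topology %||% "sim8"),
          coupling = coupling_spec(chr("coupling", cfg$coupling %||% "linear")),
          n_obs = int("n-obs", cfg$n_obs %||% 500L),
          snr_db_levels = snr,
          n_runs = int("runs", cfg$n_runs %||% 200L),
          methods = methods, seed = seed)
        log_msg("simulate-benchmark: ", config$n_runs, " runs, coupling ",
                config$coupling$fun, file = logf)
        params <- inference_params(n_perm = int("n-perm", 19L), seed = seed)
        rec <- run_benchmark(config, params)
        utils::write.table(rec, file.path(out, "records.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        agg <- aggregate_and_compare(rec)
        utils::write.table(agg$summary, file.path(out, "summary.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        write_manifest(out, list(subcommand = sub, topology = config$topology$name,
                                 coupling = config$coupling$fun,
                                 n_obs = config$n_obs, snr_db_levels = snr,
                                 n_runs = config$n_runs, methods = methods,
                                 n_perm = params$n_perm, seed = seed))
        log_msg("wrote ", nrow(rec), " records to ", out, file = logf)
        0L
      },
      "synth-cohorts" = {
        out <- chr("out"); if (is.null(out)) stop("--out is required")
        seed <- int("seed", 1L)
        par <- paradigm_spec(n_stimuli = int("stimuli", 100L),
                             n_targets = int("targets", 20L),
                             n_runs = int("runs", 4L), seed = seed)
        coh <- generate_cohorts(int("hc", 25L), int("scz", 23L),
                                paradigm = par, seed = seed)
        for (grp in c("hc", "scz")) {
          for (i in seq_along(coh[[grp]])) {
            d <- file.path(out, grp, sprintf("subject%02d", i))
            dir.create(d, recursive = TRUE, showWarnings = FALSE)
            sj <- coh[[grp]][[i]]
            write_series(sj$series, file.path(d, "series.tsv"))
            utils::write.table(sj$events, file.path(d, "events.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE)
          }
        }
        utils::write.table(coh$truth, file.path(out, "planted_edges.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        write_manifest(out, list(subcommand = sub, n_hc = length(coh$hc),
                                 n_scz = length(coh$scz),
                                 n_stimuli = par$n_stimuli,
                                 n_targets = par$n_targets,
                                 n_runs = par$n_runs, seed = seed))
        0L
      },
      "infer-network" = {
        inf <- chr("in"); outf <- chr("out")
        if (is.null(inf) || is.null(outf)) stop("--in and --out are required")
        series <- read_series(inf)
        params <- inference_params(estimator = chr("estimator", "plugin"),
                                   n_bins = int("bins", 3L),
                                   n_perm = int("n-perm", 199L),
                                   alpha = num("alpha", 0.05),
                                   seed = int("seed", 1L))
        net <- suppressWarnings(
          infer_by_method(series, chr("method", "mte"), params))
        write_network(net, outf)
        0L
      },
      "compare-groups" = {
        d1 <- chr("hc-dir"); d2 <- chr("scz-dir"); out <- chr("out")
        if (is.null(d1) || is.null(d2) || is.null(out)) {
          stop("--hc-dir, --scz-dir and --out are required")
        }
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        alpha <- num("alpha", 0.05)
        params <- inference_params(alpha = alpha, n_perm = int("n-perm", 19L),
                                   max_order = int("max-order", 2L),
                                   seed = int("seed", 1L))
        method <- chr("method", "gca")
        load_group <- function(d) {
          dirs <- list.dirs(d, recursive = FALSE)
          lapply(dirs, function(sd) {
            s <- read_series(file.path(sd, "series.tsv"))
            ev <- utils::read.table(file.path(sd, "events.tsv"), sep = "\t",
                                    header = TRUE, stringsAsFactors = FALSE)
            ep <- reject_artifacts(preprocess_eeg(s, ev))
            subject_network(ep, method, params)
          })
        }
        hc <- load_group(d1); scz <- load_group(d2)
        cmp <- group_difference(hc, scz, alpha)
        edges <- which(cmp$significant != 0, arr.ind = TRUE)
        df <- data.frame(
          source = cmp$labels[edges[, 1L]], target = cmp$labels[edges[, 2L]],
          t = cmp$t[edges], p_adjusted = cmp$p_adjusted[edges],
          direction = ifelse(cmp$t[edges] > 0, "hc_gt_scz", "scz_gt_hc"))
        utils::write.table(df, file.path(out, "group_edges.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        od <- data.frame(channel = cmp$labels,
                         hc_gt_scz = as.integer(out_degree(cmp$hc_gt_scz)),
                         scz_gt_hc = as.integer(out_degree(cmp$scz_gt_hc)))
        utils::write.table(od, file.path(out, "out_degree.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        write_manifest(out, list(subcommand = sub, method = method,
                                 alpha = alpha, n_hc = length(hc),
                                 n_scz = length(scz),
                                 seed = int("seed", 1L)))
        0L
      },
      "report" = {
        rf <- chr("records"); out <- chr("out")
        if (is.null(rf) || is.null(out)) stop("--records and --out are required")
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        rec <- utils::read.table(rf, sep = "\t", header = TRUE,
                                 stringsAsFactors = FALSE)
        agg <- aggregate_and_compare(rec, alpha = num("alpha", 0.05))
        utils::write.table(agg$summary, file.path(out, "summary.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(agg$tests, file.path(out, "method_tests.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        0L
      },
      { cli_usage(); stop("unknown subcommand '", sub, "'") })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  invisible(status)
}
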