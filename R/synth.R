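#' Oddball paradigm specification
#'
#' Defaults mirror a standard visual P300 protocol: runs of 100 stimuli with
#' 20 rare targets among 80 standards, each trial a 750 ms cue, 150 ms
#' stimulus and 1,000 ms break (1,900 ms per trial).
#'
#' @param n_stimuli stimuli per run.
#' @param n_targets targets per run (0 < n_targets < n_stimuli).
#' @param n_runs task runs per subject.
#' @param cue_ms,stimulus_ms,break_ms trial phase durations in ms (> 0).
#' @param seed integer seed for the random stimulus order.
#' @return A `paradigm_spec`.
#' @export
paradigm_spec <- function(n_stimuli = 100L, n_targets = 20L, n_runs = 4L,
                          cue_ms = 750, stimulus_ms = 150, break_ms = 1000,
                          seed = 1L) {
  if (!(n_targets > 0L && n_targets < n_stimuli)) {
    stop("need 0 < n_targets < n_stimuli")
  }
  if (any(c(cue_ms, stimulus_ms, break_ms) <= 0)) stop("durations must be > 0")
  structure(list(n_stimuli = as.integer(n_stimuli),
                 n_targets = as.integer(n_targets), n_runs = as.integer(n_runs),
                 cue_ms = cue_ms, stimulus_ms = stimulus_ms,
                 break_ms = break_ms, seed = seed),
            class = "paradigm_spec")
}

#' Generate an oddball event sequence
#'
#' Targets are placed at random positions within each run (deterministic
#' under the spec seed). Stimulus onsets fall `cue_ms` into each trial, so
#' consecutive onsets are `cue_ms + stimulus_ms + break_ms` apart.
#'
#' @param spec a [paradigm_spec()].
#' @return Data frame with columns `run`, `time_ms` (global stimulus onset)
#'   and `label` (`"standard"`/`"target"`).
#' @export
generate_paradigm <- function(spec) {
  trial_ms <- spec$cue_ms + spec$stimulus_ms + spec$break_ms
  out <- list()
  for (r in seq_len(spec$n_runs)) {
    lab <- rep("standard", spec$n_stimuli)
    pos <- with_seed(derive_seed(spec$seed, "paradigm", r),
                     sample.int(spec$n_stimuli, spec$n_targets))
    lab[pos] <- "target"
    onset <- (r - 1L) * spec$n_stimuli * trial_ms +
      (seq_len(spec$n_stimuli) - 1L) * trial_ms + spec$cue_ms
    out[[r]] <- data.frame(run = r, time_ms = onset, label = lab)
  }
  do.call(rbind, out)
}

default_base_edges <- function() {
  rbind(c("Fp1", "F3"), c("Fp2", "F4"), c("F7", "T3"), c("F8", "T4"),
        c("T5", "O1"), c("T6", "O2"), c("P3", "O1"), c("P4", "O2"))
}

default_hc_extra_edges <- function() {
  rbind(c("Fp1", "P3"), c("F3", "P3"), c("F4", "P4"), c("F3", "C3"))
}

#' Group-differentiated coupling specification
#'
#' Describes the synthetic cohorts' stated world: a base directed network
#' shared by both groups plus extra frontal/prefrontal-to-parietal edges
#' active (or stronger) in healthy controls only — the direction of the
#' group difference the P300 literature reports — together with the evoked
#' response and background-noise parameters.
#'
#' @param base_edges two-column character matrix (source, target) of edges
#'   present in both groups.
#' @param hc_extra_edges two-column character matrix of HC-only edges;
#'   must be disjoint from `base_edges`.
#' @param base_gain lagged coupling gain of base edges (both groups).
#' @param extra_gain_hc,extra_gain_scz gain of the extra edges per group
#'   (>= 0; SCZ default 0 = absent).
#' @param p300_amp_uv named vector `c(hc=, scz=)`: evoked peak amplitude
#'   (microvolts) on centro-parietal channels.
#' @param p300_latency_ms named vector of evoked peak latencies.
#' @param coupling_lag_ms conduction delay of the planted directed coupling
#'   in ms (physiological cortico-cortical range).
#' @param noise_sd_uv standard deviation of the background activity.
#' @param ar_coef lag-1 autocorrelation of the pink-like background.
#' @param artifact_rate probability in `[0, 1)` that a trial receives an
#'   injected artifact (see [inject_artifacts()]).
#' @param subject_jitter_sd log-normal sd of mild between-subject gain
#'   jitter.
#' @return A `group_effect_spec`.
#' @export
group_effect_spec <- function(base_edges = default_base_edges(),
                              hc_extra_edges = default_hc_extra_edges(),
                              base_gain = 0.5,
                              extra_gain_hc = 0.6, extra_gain_scz = 0,
                              p300_amp_uv = c(hc = 8, scz = 4),
                              p300_latency_ms = c(hc = 350, scz = 380),
                              coupling_lag_ms = 8,
                              noise_sd_uv = 10, ar_coef = 0.95,
                              artifact_rate = 0, subject_jitter_sd = 0.1) {
  key <- function(m) paste(m[, 1L], m[, 2L])
  if (length(intersect(key(base_edges), key(hc_extra_edges)))) {
    stop("hc_extra_edges must be disjoint from base_edges")
  }
  if (extra_gain_hc < 0 || extra_gain_scz < 0 || base_gain < 0) {
    stop("gains must be >= 0")
  }
  if (!(artifact_rate >= 0 && artifact_rate < 1)) {
    stop("artifact_rate must lie in [0, 1)")
  }
  structure(list(base_edges = base_edges, hc_extra_edges = hc_extra_edges,
                 base_gain = base_gain, extra_gain_hc = extra_gain_hc,
                 extra_gain_scz = extra_gain_scz, p300_amp_uv = p300_amp_uv,
                 p300_latency_ms = p300_latency_ms,
                 coupling_lag_ms = coupling_lag_ms, noise_sd_uv = noise_sd_uv,
                 ar_coef = ar_coef, artifact_rate = artifact_rate,
                 subject_jitter_sd = subject_jitter_sd),
            class = "group_effect_spec")
}

#' Generate one synthetic EEG subject
#'
#' Sixteen channels at 1,000 Hz: per-channel autoregressive background,
#' lagged linear influence along the base edges (both groups) and the
#' HC-extra edges (per-group gain), and a P300-like positive deflection on
#' centro-parietal channels after each target (group-specific amplitude and
#' latency). Returns the exact planted directed network as ground truth.
#'
#' @param group `"hc"` or `"scz"`.
#' @param effects a [group_effect_spec()].
#' @param paradigm a [paradigm_spec()].
#' @param seed integer seed.
#' @param gain_scale multiplicative jitter on coupling gains (used by
#'   [generate_cohorts()]).
#' @return List with `series` (a [multichannel_series()] at 1,000 Hz,
#'   microvolts), `events` (data frame), `truth` (a
#'   [ground_truth_network()] over the montage) and `group`.
#' @export
generate_subject <- function(group = c("hc", "scz"),
                             effects = group_effect_spec(),
                             paradigm = paradigm_spec(), seed = 1L,
                             gain_scale = 1) {
  group <- match.arg(group)
  chans <- default_montage()
  sr <- 1000
  events <- generate_paradigm(paradigm)
  trial_ms <- paradigm$cue_ms + paradigm$stimulus_ms + paradigm$break_ms
  L <- as.integer(paradigm$n_runs * paradigm$n_stimuli * trial_ms * sr / 1000)
  nch <- length(chans)
  extra_gain <- if (group == "hc") effects$extra_gain_hc else effects$extra_gain_scz
  with_seed(derive_seed(seed, "subject", group), {
    core <- matrix(0, nch, L)
    for (i in seq_len(nch)) {
      innov_sd <- effects$noise_sd_uv * sqrt(1 - effects$ar_coef^2)
      core[i, ] <- as.numeric(stats::filter(stats::rnorm(L, sd = innov_sd),
                                            effects$ar_coef, method = "recursive"))
    }
    obs <- core
    lag <- max(1L, as.integer(round(effects$coupling_lag_ms * sr / 1000)))
    add_edges <- function(edges, gain) {
      if (!nrow(edges) || gain <= 0) return(invisible())
      for (r in seq_len(nrow(edges))) {
        s <- match(edges[r, 1L], chans); t <- match(edges[r, 2L], chans)
        obs[t, (lag + 1L):L] <<- obs[t, (lag + 1L):L] +
          gain * core[s, 1L:(L - lag)]
      }
    }
    add_edges(effects$base_edges, effects$base_gain * gain_scale)
    add_edges(effects$hc_extra_edges, extra_gain * gain_scale)
    # evoked P300 on centro-parietal channels after each target
    amp <- effects$p300_amp_uv[[group]]
    lat <- effects$p300_latency_ms[[group]]
    bump_t <- 0:700
    bump <- amp * exp(-((bump_t - lat)^2) / (2 * 60^2))
    evoked_ch <- match(c("C3", "C4", "P3", "P4"), chans)
    for (on in events$time_ms[events$label == "target"]) {
      idx <- as.integer(round(on)) + bump_t + 1L
      ok <- idx >= 1L & idx <= L
      for (ch in evoked_ch) obs[ch, idx[ok]] <- obs[ch, idx[ok]] + bump[ok]
    }
    truth_edges <- effects$base_edges
    if (extra_gain > 0) truth_edges <- rbind(truth_edges, effects$hc_extra_edges)
    A <- matrix(0L, nch, nch, dimnames = list(chans, chans))
    for (r in seq_len(nrow(truth_edges))) {
      A[truth_edges[r, 1L], truth_edges[r, 2L]] <- 1L
    }
    subject <- list(series = multichannel_series(obs, chans, sr),
                    events = events,
                    truth = ground_truth_network(A, paste0(group, "_planted")),
                    group = group)
    if (effects$artifact_rate > 0) {
      subject <- inject_artifacts(subject, effects$artifact_rate,
                                  seed = derive_seed(seed, "artifacts"))$subject
    }
    subject
  })
}

#' Inject supra-threshold artifact excursions
#'
#' For each target trial independently with probability `rate`, adds a
#' transient half-sine excursion of the given amplitude on one random
#' channel inside the trial's epoch window, and reports which trials were
#' hit (so rejection behaviour can be verified exactly).
#'
#' @param subject a subject list from [generate_subject()] (or a list with
#'   `series` and `events`).
#' @param rate per-trial injection probability.
#' @param amplitude_uv excursion amplitude in microvolts (> 0).
#' @param seed integer seed.
#' @return List with the modified `subject` and `injected` (indices into the
#'   subject's target trials).
#' @export
inject_artifacts <- function(subject, rate, amplitude_uv = 150, seed = 1L) {
  if (amplitude_uv <= 0) stop("amplitude_uv must be positive")
  v <- subject$series$values
  onsets <- subject$events$time_ms[subject$events$label == "target"]
  injected <- integer(0)
  with_seed(seed, {
    for (tr in seq_along(onsets)) {
      if (stats::runif(1) >= rate) next
      injected <- c(injected, tr)
      ch <- sample.int(nrow(v), 1L)
      idx <- as.integer(round(onsets[tr])) + 300L + 0:49
      idx <- idx[idx >= 1L & idx <= ncol(v)]
      v[ch, idx] <- v[ch, idx] + amplitude_uv * sin(pi * seq_along(idx) / length(idx))
    }
  })
  subject$series <- multichannel_series(v, subject$series$labels,
                                        subject$series$sample_rate)
  list(subject = subject, injected = injected)
}

#' Generate two synthetic cohorts
#'
#' Defaults echo the study design this generator stands in for: 25 healthy
#' controls and 23 patients. Per-subject seeds derive from the root seed and
#' gains receive mild log-normal between-subject jitter.
#'
#' @param n_hc,n_scz subjects per group (>= 2).
#' @param effects a [group_effect_spec()].
#' @param paradigm a [paradigm_spec()].
#' @param seed root seed; identical seeds give byte-identical cohorts.
#' @return List with `hc` and `scz` (lists of subjects) and `truth`
#'   (data frame of planted edges with group tags).
#' @export
generate_cohorts <- function(n_hc = 25L, n_scz = 23L,
                             effects = group_effect_spec(),
                             paradigm = paradigm_spec(), seed = 1L) {
  if (n_hc < 2L || n_scz < 2L) stop("need at least 2 subjects per group")
  gen_group <- function(group, n) {
    lapply(seq_len(n), function(i) {
      sseed <- derive_seed(seed, group, i)
      jit <- with_seed(derive_seed(sseed, "jitter"),
                       exp(stats::rnorm(1, sd = effects$subject_jitter_sd)))
      generate_subject(group, effects, paradigm, seed = sseed, gain_scale = jit)
    })
  }
  hc <- gen_group("hc", n_hc)
  scz <- gen_group("scz", n_scz)
  truth <- rbind(
    data.frame(source = effects$base_edges[, 1L],
               target = effects$base_edges[, 2L], group = "both"),
    data.frame(source = effects$hc_extra_edges[, 1L],
               target = effects$hc_extra_edges[, 2L], group = "hc_extra"))
  list(hc = hc, scz = scz, truth = truth)
}
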