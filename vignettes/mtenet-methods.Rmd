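---
title: "Directed network inference with mtenet: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed network inference with mtenet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtenet)
```

# The problem

Effective connectivity asks a directed question of multichannel time series:
which processes *drive* which? `mtenet` implements and compares three answers
on a common footing:

* **GCA** — conditional multivariate Granger causality. A vector
  autoregressive (MVAR) model of order $p$ is fitted by per-equation ordinary
  least squares; the influence of channel $i$ on channel $j$ is
  $\log(\sigma^2_{\text{restricted}} / \sigma^2_{\text{full}})$, where the
  restricted model omits $i$'s lags from $j$'s equation, with a nested-model
  F-test for significance and AIC
  ($n\log\det\Sigma + 2pn^2$) for order selection.
* **BVTE** — bivariate transfer entropy. For each ordered pair, the
  information the source's past adds about the target's present beyond the
  target's own past,
  $TE_{Y\to X} = h_2 - h_1$ with
  $h_1 = -\sum p(x_{n+1}, x_n, y_n)\log_2 p(x_{n+1}\mid x_n, y_n)$ and
  $h_2$ the same quantity conditioned on $x_n$ only. Model-free, hence
  sensitive to non-linear coupling, but blind to the multivariate context:
  two-hop chains produce spurious "cascade" edges and purely synergistic
  parents are invisible.
* **MTE** — multivariate (conditional) transfer entropy. TE from a source
  into a target conditioned on the target's *other relevant sources*
  $Z$: $TE_{X\to Y\mid Z}$. Removes redundant/cascade edges and can credit
  synergistic parent sets.

All adjacency matrices in the package are oriented **row = source,
column = target**, and every writer annotates this in its header.

# Estimators

Transfer entropy requires conditional entropy rates of continuous data. Two
estimators are provided:

* **Plug-in (default)**: each channel is discretized (default 3 quantile
  bins, rank-based so ties share a bin and continuous data get near-equal
  occupancy), and the TE sum is evaluated over observed symbol
  configurations with base-2 logarithms — results in bits. Deterministic,
  fast, and exactly checkable on discrete worked examples (a noiseless
  binary copy channel gives 1 bit; fair-bit XOR gives 0 bivariately and
  1 bit conditionally). Its weakness is resolution: a coupling through
  $\cos(2\pi x)$ oscillates ~6 periods across a standardized signal's range,
  so 3-bin symbols retain almost none of it. Negative finite-sample
  estimates are clamped to zero when reported as edge weights; the raw
  value is kept in the `te_computation`.
* **Gaussian**: $\tfrac12\log_2$ of the ratio of least-squares residual
  variances of the two nested regressions. On jointly Gaussian (linear VAR)
  data this is exactly the Granger statistic divided by $2\ln 2$ — an
  identity the test suite verifies to $10^{-6}$ against independent OLS
  oracles and `fit_mvar`.

The defining equations condition on the *entire* past of each process; we
use finite uniform embedding instead (`embedding_spec`): `k_target` target
lags, `l_source` source/condition lags, spaced `delay` samples, defaults
1/1/1 to match the single-lag notation of the definitions, configurable
upward. Kraskov-style nearest-neighbour estimation and non-uniform embedding
optimization are deliberately out of scope.

## Surrogate significance

No estimator has a usable analytic null here, so edges are tested against
**circular-shift surrogates**: the source is rotated by a uniformly random
offset in $[n/8,\ 7n/8]$ samples, which preserves its autocorrelation but
destroys any cross-coupling. P-values use the permutation +1 correction
$p = (1 + \#\{TE^{surr} \ge TE^{obs}\})/(1 + n_{perm})$, so $n_{perm} = 19$
is the minimum that can resolve $\alpha = 0.05$. Offsets are drawn *without*
replacement whenever the admissible range allows: duplicated rotations waste
null resolution and measurably inflate the false-selection rate. All
surrogate streams derive deterministically from one root seed via
per-(target, step) substreams, so identical seeds give identical networks.

# The greedy MTE search

The relevant-source set of each target is unknown and must be inferred. Per
target:

1. **Forward**: among the remaining candidates, take the one with maximal
   conditional TE given the already-selected sources; keep it only if
   surrogate-significant at `alpha`, otherwise stop. No max-statistic
   correction is applied across candidates (per-test alpha), which makes the
   first step mildly anti-conservative by construction.
2. **Synergy rescue** (package extension, `synergy_pairs = TRUE`): if the
   forward phase selected *nothing*, candidate **pairs** are evaluated
   jointly and the best pair is tested against a max-statistic surrogate
   null (the maximum over all pairs is recomputed for every shifted
   surrogate, controlling the family-wise error of the search). This step
   exists because a purely synergistic parent set — the XOR target is the
   canonical case — has exactly zero single-source TE, so no sequential
   single-candidate scheme can ever enter its forward phase. Without it,
   "multivariate TE does not miss synergistic interactions" would be false
   of this implementation.
3. **Backward pruning**: each selected source is re-tested conditioned on
   the remaining selected set and dropped if no longer significant.
4. Edge weights are $TE(X\to Y \mid \text{selected}\setminus X)$, clamped at
   zero.

The sequential stopping rule trades sensitivity for specificity: a true
parent ranked below a failing candidate is never examined. This is visible
in the benchmark (below) as MTE sensitivity a few points under BVTE's, while
MTE dominates on specificity and total agreement.

# The simulation benchmark

`builtin_topology()` provides canonical 7- and 8-node ground-truth networks
(10 and 12 directed edges; exactly one bidirectional pair; every node
connected; 42 and 56 ordered-pair slots). The originals in the source study
are only drawn, never printed numerically, so these are package-defined
stand-ins with the stated qualitative properties — which is also why the
benchmark reproduces *directions* of the published comparisons, not cell
values.

Series generation (`generate_series`): linear systems follow
$x_j(t) = \sum_i a_{ij} x_i(t-1) + 0.3\,x_j(t-1) + \varepsilon_j(t)$, with
edge coefficients drawn once per run from $U(0.3, 0.6)$ and
$\varepsilon \sim N(0, 1)$; non-linear systems replace $x_i(t-1)$ with one
of five coupling functions: $C(x) = \cos x + \sin x$,
$f(x) = 21.6x/(1+e^{-4x})$ (the printed "2.40×9x" numerator read literally;
a `compact` 2.409x mode is selectable), $\cos(2\pi x)$,
$H(x) = e^{\sin(2\pi x)}$, and the logistic $S(x) = 1/(1+e^{-x})$.

Two numerical choices stabilize this system and are made a priori, not tuned:

* each coupling function is **standardized** (zero mean, unit variance under
  standard-normal input, moments by deterministic quadrature), because the
  raw $f$ has asymptotic slope 21.6 and diverges on any cyclic topology;
* the coefficient matrix is rescaled so the *linearized* dynamics
  (linear gain of the standardized function times the coefficient matrix,
  plus the 0.3 self-term) have spectral radius at most 0.9. Non-finite
  generation aborts with an error rather than returning garbage.

A 200-sample burn-in is discarded, non-linear output channels are
standardized, and `add_noise` contaminates every channel with white Gaussian
noise at a target SNR, defined as $10\log_{10}(P_{signal}/P_{noise})$ dB
(noise sd $= \sigma_{signal}\,10^{-SNR/20}$). Defaults follow the study
design: 500 observations, SNR levels $-10, -5, 5, 10$ dB, 200 repetitions
(tests and examples scale the repetitions and surrogate counts down and say
so).

Scoring (`metrics`): confusion counts over all ordered off-diagonal pairs,
sensitivity $= 100\,TP/(TP+FN)$, specificity $= 100\,TN/(TN+FP)$ (zero
denominators yield `NA` markers, excluded from aggregation), edges recovered
$= TP + TN$ (the "agreement" reading — published magnitudes near 50 of 56
exceed any plausible true-edge count, so a true-positive reading cannot
match), and the adjacency bias
$\Delta Y = \lVert Y_c - Y_b\rVert_F / \lVert Y_c \rVert_F$ between the
noise-free and contaminated estimates (the norm is unspecified in the
source; Frobenius is chosen for scale invariance). Summaries are
mean ± *sample* sd; method pairs are compared by paired two-sided t-tests
across shared run indices ("independent paired t-test" in the source is
contradictory; pairing matches the shared-realization design), with $p = 1$
by convention for identical vectors.

## What a green benchmark does and does not establish

With the plug-in estimator at its spec'd defaults, the linear block behaves
as published (every method ≥ 85% sensitivity at 10 dB; all three methods
recover clean linear systems at ≥ 90% sensitivity). The full published
ordering MTE ≥ BVTE ≥ GCA on every metric for every non-linear coupling does
**not** emerge, for reasons that are structural rather than parametric:
the standardized $C$, $S$ and $f$ couplings retain strong linear components
that an exact F-test detects essentially always, while a 3-bin histogram
estimator cannot; and the even couplings $\cos(2\pi x)$ and
$e^{\sin(2\pi x)}$ are nearly invisible to coarse binning (and exactly
invisible to linear regression), leaving all methods near the false-alarm
floor. The published ordering was obtained with nearest-neighbour (KSG)
estimators, which are out of scope here. The acceptance suite states the
ordering as-is and lets the unattainable comparisons fail visibly; MTE's
specificity and total-agreement advantages over BVTE, and its linear-block
performance, hold throughout.

# The P300 pipeline

`preprocess_eeg` applies a fixed-order chain to a continuous 16-channel
recording (10–20 montage, 1,000 Hz): zero-phase 0.5–30 Hz band-pass →
target-trial epochs over $[-200, 800)$ ms (1,000 samples) → per-channel
baseline subtraction over $[-200, 0)$ ms → average re-reference.
`reject_artifacts` then drops any trial whose absolute amplitude exceeds
±100 µV (idempotent). Two substitutions deserve note:

* **Filter realization.** No IIR filter-design library is available in the
  target environment, so the zero-phase 4th-order Butterworth band-pass is
  realized in the frequency domain: the FFT spectrum is multiplied by the
  *squared* Butterworth magnitude — exactly the forward–backward
  (`filtfilt`) response of the named filter, ~36 dB down at 50 Hz with a
  30 Hz edge, and zero-phase by construction.
* **Reference.** The source pipeline uses REST, which needs a head model and
  is out of scope; the average reference substitutes. Unlike REST, the
  average reference zeroes the channel sum, making the full-conditional MVAR
  design exactly rank-deficient — every source's lags become linear
  combinations of the others', and all conditional Granger weights collapse
  to zero. When `infer_gca_network` detects exact collinearity it therefore
  switches to leave-one-out conditioning: for each ordered pair one fixed
  channel outside the pair is excluded from the conditioning set, restoring
  identifiability; order selection uses the pseudo-determinant of the
  residual covariance.

`subject_network` runs the chosen method on every kept trial and averages
the weight matrices into one 16 × 16 subject network. Epochs are decimated
(default 4×, to 250 Hz) first: the data are band-limited to 30 Hz, far below
the decimated Nyquist rate, and low-order lag models resolve physiological
conduction delays (~4–20 ms) far better at 250 Hz than at the oversampled
rate. `group_difference` then applies an edgewise Welch two-sample t-test
(healthy controls vs patients; the source says only "independent t-test"),
Benjamini–Hochberg FDR across the 240 edges (the source names no FDR
procedure), and splits significant edges into disjoint direction masks by
t-sign. `out_degree` is the row sum of a mask.

# The synthetic cohort generator

The study's recordings are available only on request, so `synth` generates
a stand-in world with known ground truth:

* **Paradigm**: oddball runs of 100 stimuli (80 standards, 20 rare targets,
  randomly ordered), 750 ms cue + 150 ms stimulus + 1,000 ms break, four
  runs per subject; defaults are the published protocol, all configurable.
* **Background**: per-channel AR(1) activity (lag-1 coefficient 0.95,
  sd 10 µV) — autocorrelated, EEG-scaled, deliberately not a biophysical
  simulation (no neural-mass model, no forward-modeled scalp mixing, no
  realistic blink/EMG morphology).
* **Coupling**: lagged linear influence with an 8 ms conduction delay along
  a base edge set shared by both groups (gain 0.5) plus
  frontal/prefrontal→parietal extra edges (Fp1→P3, F3→P3, F4→P4, F3→C3)
  active only in controls (gain 0.6 vs 0.0) — the direction of the group
  difference reported for this paradigm. Gains get mild log-normal
  between-subject jitter (sd 0.1).
* **Evoked response**: a P300-like Gaussian bump on C3/C4/P3/P4
  (peak 8 µV at 350 ms for controls, 4 µV at 380 ms for patients),
  reflecting the attenuated-P300 phenomenon.
* **Cohorts**: default 25 controls and 23 patients, per-subject seeds
  derived from one root seed; `inject_artifacts` plants supra-threshold
  excursions in randomly chosen trials and returns their indices so
  rejection behaviour can be verified exactly.

Default gains were chosen so that a 20-per-group cohort detects the planted
edges with power well above 0.8 through the *full* pipeline — a generator
calibration made once, not a published value; trial counts surviving
rejection and per-subject SNR are likewise not published, so defaults are
calibrated to pipeline power. A green end-to-end test therefore establishes
that the pipeline recovers a known planted difference of plausible
magnitude — not that it reproduces the clinical dataset.

# Known limitations

* Plug-in TE with few bins underestimates strongly non-monotone couplings;
  the KSG estimator that would fix this is out of scope.
* The greedy forward search can stop before exhausting true parents
  (sensitivity cost); the synergy rescue only covers pairs, not higher-order
  synergies.
* Circular-shift surrogates assume approximate stationarity within a series.
* The `f` coupling's printed "2.40×9x" numerator is ambiguous; both the
  literal (21.6x, default) and compact (2.409x) readings are implemented.
* A channel named "C2" appears in the source's out-degree discussion but not
  in its 16-channel montage; the montage here follows the recording
  description.
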