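# mtenet

Directed ("effective") network inference from multichannel time series, for
people comparing linear and information-theoretic causality measures —
e.g. EEG effective-connectivity studies contrasting clinical groups, or
benchmarking network-recovery methods on simulated coupled systems.

Three methods share one interface and one `directed_network` container
(orientation: **row = source, column = target**):

| method | statistic | significance |
|---|---|---|
| `infer_gca_network` | conditional Granger causality: log variance ratio of nested MVAR models, AIC order selection | nested-model F-test |
| `infer_bvte_network` | bivariate transfer entropy `TE(X→Y) = h2 − h1` (bits) for every ordered pair | circular-shift surrogates |
| `infer_mte_network` | multivariate transfer entropy `TE(X→Y \| Z)` with greedy relevant-source selection, backward pruning and a synergy-pair rescue | circular-shift surrogates |

Transfer entropy comes with two estimators: a plug-in histogram estimator
(default; quantile bins, exact on discrete worked examples) and a Gaussian
estimator that equals the Granger statistic divided by `2·ln 2` on linear
VARs (verified to 1e−6 in the tests).

Around the estimators the package ships:

* **simbench** — canonical 7/8-node ground-truth topologies, linear plus
  five non-linear coupling generators (`C`, `f`, `cosinusoidal`, `H`, `S`),
  SNR-controlled Gaussian contamination, and a fully seeded benchmark
  harness (`run_benchmark`) scored by confusion counts, sensitivity,
  specificity, edges recovered and adjacency bias `ΔY = ‖Yc−Yb‖/‖Yc‖`.
* **eeg** — a P300 oddball pipeline: zero-phase 0.5–30 Hz band-pass, 1-s
  target epochs, baseline correction, average re-reference, ±100 µV artifact
  rejection, per-trial network estimation averaged into 16×16 subject
  networks, edgewise Welch tests with Benjamini–Hochberg FDR between groups,
  and out-degree topology summaries.
* **synth** — a synthetic two-group 16-channel EEG cohort generator with
  planted, group-differentiated frontal→parietal coupling and known ground
  truth (a stand-in for clinical recordings that are not publicly
  deposited).
* **interface** — text round-trips for series and networks, and a CLI
  (`run_cli` / `inst/cli/mtenet.R`) with subcommands `simulate-benchmark`,
  `synth-cohorts`, `infer-network`, `compare-groups`, `report`.

## Worked example

Generate a 3-node chain with logistic (non-linear) coupling, contaminate it
at 10 dB SNR, and recover the network with multivariate transfer entropy:

```r
library(mtenet)

gt  <- ground_truth_network(rbind(c(0, 1, 0),
                                  c(0, 0, 1),
                                  c(0, 0, 0)), "chain3")
gen   <- generate_series(gt, coupling_spec("S"), n_obs = 500, seed = 2)
noisy <- add_noise(gen$series, snr_db = 10, seed = 102)

net <- infer_mte_network(noisy, inference_params(n_perm = 99, seed = 202))
print(net)
#> <directed_network> mte, 3 nodes, 2 significant edges (row = source)
round(net$weights, 3)
#>    N1    N2  N3
#> N1  0 0.119 0.0
#> N2  0 0.000 0.1
#> N3  0 0.000 0.0

cc <- confusion_counts(net, gt)
sprintf("edges recovered: %d/6, sensitivity %.1f%%, specificity %.1f%%",
        edges_recovered(net, gt), sensitivity(cc), specificity(cc))
#> "edges recovered: 6/6, sensitivity 100.0%, specificity 100.0%"
```

The two planted edges N1→N2 and N2→N3 are recovered with weights of ~0.1
bits each — the information the source's immediate past carries about the
target's next value beyond the target's own history — and no spurious edge
survives the surrogate test, so all 6 ordered pairs agree with the ground
truth.

The same comparison at scale (all couplings, 4 SNR levels, many runs,
paired method tests) runs via:

```sh
Rscript inst/cli/mtenet.R simulate-benchmark --out bench --coupling S --runs 20 --seed 1
Rscript inst/cli/mtenet.R report --records bench/records.tsv --out bench
```

and the synthetic clinical contrast via `synth-cohorts` + `compare-groups`.

## Documentation

The methods vignette (`vignettes/mtenet-methods.Rmd`) documents the models
and assumptions, every tunable default, what the synthetic generators do and
do not emulate, the numerical design choices (estimator defaults, surrogate
scheme, rank-deficiency handling under average reference, coupling
standardization), and known limitations.
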