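# dfcnet

Dynamic functional connectivity networks for narrative classification, with
Shapley-value subnetwork attribution.

## What this package is for

When people listen to or watch a story, the coupling between brain regions
reorganizes over the course of the narrative. dfcnet is for researchers who
want to ask, from region-of-interest (ROI) fMRI time series: *can the
modality (audio vs. movie) and content (e.g. airport vs. restaurant script)
of a narrative be decoded from time-resolved functional connectivity — and
which brain subnetworks carry that signal?*

The package implements the full analysis as tested, reusable pieces:

- **Network construction** — nuisance regression, zero-phase band-pass
  filtering (0.01–0.08 Hz), sliding-window Pearson correlation (30 s
  windows, 7.5 s overlap by default), and per-edge Z-normalization fitted
  on training data only. A run becomes a tensor
  `X ∈ [−1,1]^{R×R×T}`: one `R×R` connectivity matrix per window.
- **Classifier** — a single convolutional layer whose filter spans all
  region pairs and slides only along time
  (`Y_{k,c} = ReLU(Σ_{i,j,p} X_{i,j,k+p−1} W_{i,j,p,c} + b_c)`), global
  max-pooling over temporal positions (`Z_c = max_k Y_{k,c}`), and an MLP
  head `C → 64 → 32 → n_classes`. With filter length `τ = 1` the model is
  exactly invariant to window order; with `τ > 1` it can exploit
  inter-window structure. Training: Adam, batch size 1, repeated
  stratified 80/20 splits with mean ± sd reporting.
- **Shapley attribution** — subnetworks of a parcellation are players of a
  cooperative game whose characteristic function `v(S)` is the trained
  model's test accuracy when all subnetworks outside `S` are masked to
  zero (the per-edge mean after Z-normalization). Exact enumeration over
  all `2^|N|` coalitions for small player sets, unbiased permutation
  sampling for large ones, aggregated across training repetitions.
- **Controls** — independent/common time-series shuffling, network-window
  shuffling, and a static (whole-run) connectivity baseline, all seeded
  and retrained, to quantify what temporal structure contributes.
- **Synthetic data** — a covariance block-model generator that plants a
  stationary modality effect in chosen subnetworks and encodes content
  purely in the *order* of latent connectivity states, so every stage of
  the pipeline (including the controls' directional predictions) is
  testable without imaging data.

## Worked example

Generate a small planted-effect dataset (modality effect in subnetwork 0,
content order-coded across subnetworks 1 and 2), build temporal networks,
train the classifier, and attribute its accuracy to subnetworks:

```r
library(dfcnet)

cfg <- sim_config(n_subjects = 8, n_narratives_per_subject = 8,
                  n_rois = 30, subnetwork_sizes = c(10, 10, 10),
                  modality_effect_subnets = 0L,
                  content_effect_subnets = c(1L, 2L),
                  seed = 42)
dataset <- make_dataset(cfg)
networks <- lapply(dataset$runs, build_temporal_network)

y <- task_labels(dataset, "modality")
run <- run_repetitions(networks, y,
                       model_config(30, tau = 4, channels = 16),
                       train_config(learning_rate = 1e-3, epochs = 10,
                                    n_repetitions = 5, seed = 1))
run$metrics
#>     metric           value
#>   accuracy 1.000 +/- 0.000
#>  precision 1.000 +/- 0.000
#>     recall 1.000 +/- 0.000
#>         f1 1.000 +/- 0.000

shap <- attribute_subnetworks(run, networks, y, dataset$parcellation,
                              method = "exact")
shap
#> Shapley attribution (exact method, 5 repetition(s))
#>  subnetwork                phi
#>           0  0.5083 +/- 0.0712
#>           1  0.0250 +/- 0.0385
#>           2 -0.0333 +/- 0.0955
```

The planted modality subnetwork (label 0) receives essentially the entire
attribution: masking it collapses accuracy, while the other subnetworks'
average marginal contributions sit at zero within repetition noise. The
per-repetition identity `Σ_i φ_i = v(N) − v(∅)` holds to machine precision
(`attr(shap, "v_full")`, `attr(shap, "v_empty")`).

Controls follow the same pattern — e.g.
`run_control(dataset, y, control_spec("shuffle_windows"), window_spec(), model_config(30, tau = 4, channels = 16), train_config(...))`
retrains on window-shuffled networks; on order-coded content data this
collapses accuracy to chance while leaving modality decoding intact.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/run-pipeline.R` (YAML config in, JSON report out);
`run_pipeline()` / `experiment_config()` are the programmatic equivalent.

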