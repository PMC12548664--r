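---
title: "Temporal brain networks, narrative classification, and Shapley attribution: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dfcnet methods}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

During naturalistic tasks such as listening to or watching a story, the
interesting signal is not only *where* activity occurs but *how the coupling
between regions evolves*. dfcnet models a run of region-of-interest (ROI)
BOLD time series as a **temporal brain network**: a tensor
$X \in [-1,1]^{R \times R \times T}$ whose slice $X_{\cdot\cdot t}$ is the
Pearson correlation matrix of the ROI signals inside sliding window $t$. A
classifier is trained to predict, from $X$, the **modality** of a narrative
(audio vs. movie), its **content** (airport vs. restaurant script), or both
jointly; Shapley values over subnetwork coalitions then attribute the
classifier's accuracy to the brain subnetworks that carry the class signal.

## Network construction

1. **Nuisance regression** (`regress_nuisance`): per-ROI ordinary least
   squares on an intercept plus supplied confound columns (e.g. motion
   parameters); residuals are exactly orthogonal to every regressor.
   Confounds are consumed, never estimated.
2. **Band-pass** (`bandpass`): order-4 Butterworth, 0.01–0.08 Hz,
   applied forward and backward (`signal::filtfilt`) so the filter is
   zero-phase and no feature is shifted in time. The series is demeaned
   before filtering; the passband excludes DC, and demeaning first keeps the
   forward–backward pass free of step transients at the run edges.
3. **Windowing** (`plan_windows`): windows of 30 s advanced by
   `window − overlap` (default overlap 7.5 s). At TR = 1.5 s this is a
   20-sample window with a 15-sample step; a trailing partial window is
   discarded. With 3-minute runs (120 samples) this yields $T = 7$ windows.
   $T$ is always data-driven — the same code yields 8 windows at 125
   samples — and the window, overlap and run length are all configurable.
4. **Correlation** (`window_correlation`): textbook Pearson per ROI pair.
   The diagonal is set to 0: self-correlation is identically 1, has zero
   variance across samples, and would otherwise break the per-edge
   normalization. A zero-variance ROI inside a window yields zero
   correlations with a warning rather than an abort, so degenerate or
   masked inputs flow through the pipeline.
5. **Z-normalization** (`fit_normalizer` / `apply_normalizer`): per edge
   $(i,j)$, the mean and standard deviation of the correlation values
   across *all training networks and all windows* are estimated, and every
   tensor entry is transformed to $(x - \mu_{ij})/\sigma_{ij}$. Population
   (1/n) moments are used, so renormalizing the training pool itself gives
   per-edge mean 0 and sd 1 exactly; with two equally frequent edge values
   0.40 and 0.45 the normalized values are exactly $\pm 1$. The point of the
   per-edge scope is that **0 becomes that edge's average connectivity**,
   which is what makes 0 a neutral masking value for the Shapley analysis;
   a per-matrix or global scaling would not have this property. Edges with
   zero variance pass through as 0 with a warning. The normalizer is fitted
   on training data only; by default `run_repetitions` refits it on each
   repetition's training split (strict leakage avoidance), with a
   `normalize = "global"` mode that fits once on the whole pool for
   fidelity with analyses that normalize before splitting.

## The classifier

A single 3-D convolutional layer whose filter spans **all** region pairs and
slides only along time, followed by global max-pooling over time and a
two-hidden-layer MLP:

$$Y_{k,c} = \sigma\Big(\sum_{i=1}^{R}\sum_{j=1}^{R}\sum_{p=1}^{\tau}
  X_{i,j,k+p-1}\, W_{i,j,p,c} + b_c\Big), \qquad
  Z_c = \max_k Y_{k,c},$$

with $\sigma$ = ReLU, $K = T - \tau + 1$ temporal positions, $C$ channels,
and an MLP head $C \to 64 \to 32 \to n_\text{classes}$ (ReLU between layers,
logits at the output). Because pooling is a max over temporal positions, a
model with $\tau = 1$ is *exactly* invariant to window order — permuting
the windows permutes the rows of $Y$ and leaves the max unchanged — while
$\tau > 1$ can exploit inter-window structure. This dichotomy is what the
permutation controls measure.

**Bias shape.** A position-indexed bias $b_{k,c}$ would destroy the
$\tau = 1$ order-invariance (different windows would see different biases),
so the default is the standard convolution convention of one bias per
channel broadcast over positions. A `position_bias = TRUE` mode exists for
sensitivity experiments.

**Implementation.** The convolution is unrolled into a
$K \times (R^2\tau)$ design matrix, making forward and backward passes
single BLAS matrix products; training uses Adam (default learning rate
1e-4), batch size 1, 20 epochs, no early stopping, weight decay or
schedule. Weights use fan-in-scaled uniform initialization. Training is
deterministic given its seed. The forward path is verified in the test
suite against a naive triple-loop evaluation of the sum above.

**Protocol.** `run_repetitions` performs `n_repetitions` (default 15)
independent stratified 80/20 splits; accuracy, and macro-averaged
precision, recall and F1 are aggregated as mean ± sd. Macro averaging is
chosen because the design is balanced (macro ≈ micro there) while staying
well-defined on unbalanced sets; a class never predicted gets precision 0,
and classes absent from a test set are excluded from the macro with a
warning. Splits are sample-level by default; a `groups` argument provides
subject-level splits, since sample-level splitting lets one subject appear
on both sides.

## Shapley attribution

Subnetworks of a parcellation (e.g. 7 functional systems over 100 ROIs) are
the *players* of a cooperative game. The characteristic function $v(S)$ is
the test accuracy of a **fixed trained model** when every subnetwork outside
$S$ is masked — rows and columns of its ROIs set to 0 in the normalized
tensor, i.e. to their average connectivity. The Shapley value

$$\phi_i(v) = \sum_{S \subseteq N\setminus\{i\}}
  \frac{|S|!\,(|N|-|S|-1)!}{|N|!}\,\big(v(S\cup\{i\}) - v(S)\big)$$

is each subnetwork's average marginal contribution over all coalition
orderings. For $|N| \le 20$, `exact_shapley` enumerates all $2^{|N|}$
coalitions (128 evaluations for 7 players) with a bitmask-keyed cache;
`sampled_shapley` draws random player orderings (default 100) and averages
marginal contributions, an unbiased estimator that shares the same cache.
`attribute_subnetworks` repeats the attribution inside every training
repetition — each repetition's model, normalizer and test split define its
own game — and reports mean ± sd per player.

Design choices made here:

- $v$ evaluates a model trained on full, unmasked data; retraining per
  coalition ($2^{7}$ retrainings per repetition) would be computationally
  incompatible with per-repetition attribution. A retrain mode can be
  emulated by calling `run_repetitions` on pre-masked tensors.
- $v(\varnothing)$ is the model's measured accuracy on the all-zero tensor
  (a constant prediction), not assumed chance; the efficiency identity
  $\sum_i \phi_i = v(N) - v(\varnothing)$ is asserted against this measured
  value at 1e-12 in every exact attribution.
- Ordering (permutation) sampling is used for the approximate method
  because it yields one marginal per player per draw and is the standard
  Monte-Carlo Shapley estimator.
- Per-ROI attribution (each ROI its own player) is available by passing a
  parcellation with one label per ROI to `sampled_shapley`'s game.

## Controls

Three seeded experiment variants isolate what temporal structure is worth:

- `shuffle_series`: permute raw time points *before* network construction.
  The default draws an independent permutation per ROI, destroying both
  inter-ROI correlation and order, which drives accuracy to chance; a
  `common_across_rois` mode applies one shared permutation, which provably
  leaves every whole-run correlation (hence static connectivity) intact
  while destroying order.
- `shuffle_windows`: permute whole connectivity windows, keeping each
  window's internal structure intact (a block permutation). Information
  carried by window *order* is destroyed; information present within single
  windows survives.
- `static_fc`: one correlation matrix over the whole run ($T = 1$, and the
  model runs with $\tau = 1$).

`run_control` applies the control at its proper stage and then retrains
across repetitions exactly like the main run; permutations are redrawn
fresh each repetition, so reported sds include permutation variability,
while split seeds match the uncontrolled run to enable paired comparisons.

## The synthetic generator

Real narrative fMRI cannot ship with a package, so `make_dataset` generates
seeded datasets whose *statistical structure* matches what the analysis
assumes: a balanced 2×2 modality-by-content design per subject, ROI signals
drawn from latent connectivity states with subnetwork-block covariance,
AR(1) temporal smoothing, and white measurement noise.

- **Modality** adds a label-signed increment ($+\varepsilon$ for modality 1,
  $-\varepsilon$ for modality 0) to the within-block covariance of the
  modality-effect subnetworks, identically in every state: modality is
  decodable from any single window, and survives window shuffling.
- **Content** is carried *only by order*: each run traverses `n_states`
  latent states (equal segments, remainder to the last), and the state's
  content increment lands on one of the content-effect blocks chosen by a
  content-specific cyclic ordering. The two contents visit the same
  multiset of blocks — the single-window marginal distribution is
  content-invariant — in different orders, so window shuffling destroys
  content decodability by construction. At least two content blocks are
  required for any order information to exist.
- **Positive-definiteness**: the baseline is unit variance with uniform
  off-diagonal covariance 0.1, which keeps $R = 100$ matrices
  well-conditioned. A signed modality decrement larger than the baseline
  makes block off-diagonals negative, which is not positive-definite at
  block sizes ≥ 10; the default modality effect is therefore 0.10 (content,
  always positive, defaults to 0.15). If a user requests larger increments
  the generator halves them until the matrix is positive-definite, warns,
  and records the shrinkage factor.
- **Defaults** emulate a cohort of 31 subjects × 16 narratives, 100 ROIs in
  7 subnetworks, 120 samples at TR 1.5 s (3-minute runs), 4 latent states,
  AR coefficient 0.3, noise sd 0.5. The AR filter runs across the whole run
  (innovations switch covariance at state boundaries) so the signal is
  continuous; with the AR coefficient and noise at 0, per-segment sample
  covariances converge to the constructed state covariances, which is the
  generator's oracle test.

**What the generator does not emulate**: hemodynamic response convolution,
scanner drift and physiological confounds (the cleaning steps are tested on
their own oracles instead), spatial voxel structure, inter-subject
variability in effect topography, and any content signal in single-window
marginals. Passing tests on this generator therefore demonstrate that the
*pipeline* recovers planted structure of the assumed kind — not that real
narrative data contain such structure.

## Problem sizes used by the tests and the acceptance script

The package's own test battery runs at deliberately reduced scale, chosen
so the full suite completes in minutes while every qualitative contrast
remains decodable: a 12-ROI/3-subnetwork fixture for unit tests; 50 ROIs in
5 subnetworks with 16 subjects × 8 narratives for planted-effect recovery
(10 master seeds, 3 repetitions each, 16 channels, learning rate 1e-3,
10–12 epochs — small-problem training settings; the 1e-4/20-epoch defaults
suit the full-scale configuration); and 30 ROIs in 3 subnetworks with 6
subjects × 8 narratives for the control battery (10 paired seeds). The
acceptance script runs the 50-ROI configuration end-to-end for all three
tasks, the exact and sampled Shapley attributions, and all three controls.

One comparison deserves a note: because the synthetic modality code is
stationary by design, static connectivity retains *all* of the modality
signal, and the static-vs-dynamic comparison is only informative when the
order-coded content task is included — the test battery therefore pools
both tasks when asserting that static connectivity does not outperform the
dynamic pipeline.

## Numerical choices and degenerate inputs

- Seeds: a single master seed fans out to every stage through a
  deterministic string-tagged hash (`sim`, `rep/i`, `train`, `shap`, …);
  identical configurations reproduce every recorded number.
- Argmax ties in prediction break toward the lowest class index.
- Max-pool gradients follow the first maximal position; ReLU subgradient at
  0 is 0.
- `n_timepoints` not divisible by `n_states`: the final segment absorbs the
  remainder (documented, not an error).
- `tau` larger than the realized `T` in `run_pipeline` is clamped to `T`
  with a message (a shape error when calling `forward` directly).
- Rank-deficient nuisance regressors: collinear columns dropped with a
  warning.

## Limitations

- The classifier is a faithful but deliberately simple architecture; no
  hyperparameter search is provided.
- Coalition masking assumes the Z-normalized representation; masking raw
  tensors with 0 would inject below-average connectivity and bias the
  model.
- $v(S)$ under a fixed model measures the model's reliance on subnetworks,
  not the information theoretically available in them (a retrained model
  could compensate for a masked subnetwork).
- Voxel-level spatial preprocessing (registration, atlas resampling) and
  NIfTI ingestion are out of scope; the pipeline starts from ROI × time
  matrices.
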