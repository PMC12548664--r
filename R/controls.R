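# Permutation and static-connectivity controls: destroy temporal structure
# at different levels (raw series vs. network windows) or collapse it
# entirely (one whole-run correlation matrix), then retrain the classifier
# so each control reports what the destroyed structure was worth.

#' Control experiment specification
#'
#' @param kind `"shuffle_series"` (permute raw time points before network
#'   construction), `"shuffle_windows"` (permute whole connectivity windows,
#'   keeping within-window structure intact), or `"static_fc"` (one
#'   correlation matrix over the entire run, `T = 1`).
#' @param seed Integer seed, recorded in every output.
#' @param series_shuffle_mode `"independent_per_roi"` draws a fresh time
#'   permutation per ROI (destroys inter-ROI correlation and order);
#'   `"common_across_rois"` applies one shared permutation (preserves
#'   instantaneous co-fluctuation, destroys order only).
#' @return A `control_spec`.
#' @export
control_spec <- function(kind = c("shuffle_series", "shuffle_windows",
                                  "static_fc"),
                         seed = 1L,
                         series_shuffle_mode = c("independent_per_roi",
                                                 "common_across_rois")) {
  structure(list(kind = match.arg(kind), seed = as.integer(seed),
                 series_shuffle_mode = match.arg(series_shuffle_mode)),
            class = "control_spec")
}

#' Permute the time axis of a raw ROI series
#'
#' The multiset of values per ROI is preserved exactly; only their temporal
#' arrangement changes.
#'
#' @param series A [roi_timeseries].
#' @param mode `"independent_per_roi"` or `"common_across_rois"`.
#' @param seed Integer seed.
#' @return A shuffled [roi_timeseries].
#' @export
shuffle_series <- function(series,
                           mode = c("independent_per_roi",
                                    "common_across_rois"),
                           seed = 1L) {
  stopifnot(inherits(series, "roi_timeseries"))
  mode <- match.arg(mode)
  l <- ncol(series$values)
  shuffled <- with_seed(seed, {
    if (mode == "common_across_rois") {
      series$values[, sample.int(l), drop = FALSE]
    } else {
      t(apply(series$values, 1L, function(row) row[sample.int(l)]))
    }
  })
  roi_timeseries(shuffled, tr = series$tr, roi_ids = series$roi_ids)
}

#' Permute the windows of a temporal network
#'
#' Slices along the time axis are permuted by a seeded random permutation;
#' each slice stays bit-identical to an original slice.
#'
#' @param net A `temporal_network`.
#' @param seed Integer seed.
#' @return A `temporal_network` with permuted windows (identity when
#'   `T = 1`).
#' @export
shuffle_windows <- function(net, seed = 1L) {
  stopifnot(inherits(net, "temporal_network"))
  tt <- dim(net$tensor)[3]
  if (tt < 2) return(net)
  perm <- with_seed(seed, sample.int(tt))
  temporal_network(net$tensor[, , perm, drop = FALSE],
                   normalization = net$normalization,
                   window_starts = net$window_starts[perm])
}

#' Static functional connectivity of a run
#'
#' One Pearson correlation matrix over the whole run; the downstream model
#' then operates with `T = 1` (and necessarily `tau = 1`).
#'
#' @param series A [roi_timeseries].
#' @return A `temporal_network` with a single slice.
#' @export
static_fc <- function(series) {
  stopifnot(inherits(series, "roi_timeseries"))
  l <- ncol(series$values)
  if (l < 3) stop_config("need at least 3 samples for static connectivity")
  mat <- window_correlation(series, c(0L, l))
  temporal_network(array(mat, dim = c(nrow(mat), ncol(mat), 1L)),
                   normalization = "raw", window_starts = 0L)
}

#' Run a control experiment end to end
#'
#' Applies the control at its proper pipeline stage (series shuffling before
#' network construction, window shuffling after, static connectivity instead
#' of windowing), then retrains and evaluates across repetitions exactly as
#' [run_repetitions()] does. Permutation controls are re-drawn fresh for
#' every repetition with seeds derived from `control$seed`, so the reported
#' sd reflects both split and permutation variability; split seeds derive
#' from `train$seed` exactly as in the uncontrolled run, enabling paired
#' comparisons.
#'
#' @param dataset A `synthetic_dataset` (or list with `runs` and `labels`).
#' @param y Integer class labels (e.g. from [task_labels()]).
#' @param control A [control_spec()].
#' @param spec A [window_spec()] (ignored for `static_fc`).
#' @param config A [model_config()]; for `static_fc` its `tau` is forced
#'   to 1.
#' @param train A [train_config()].
#' @return A `repetition_run` with the `control_spec` attached as attribute
#'   `control`.
#' @export
run_control <- function(dataset, y, control, spec = window_spec(),
                        config, train = train_config()) {
  stopifnot(inherits(control, "control_spec"))
  y <- as.integer(y)
  runs <- dataset$runs

  if (control$kind == "static_fc") {
    nets <- lapply(runs, static_fc)
    cfg <- config
    cfg$tau <- 1L
    out <- run_repetitions(nets, y, cfg, train)
    attr(out, "control") <- control
    return(out)
  }

  base_nets <- if (control$kind == "shuffle_windows")
    lapply(runs, build_temporal_network, spec = spec)
  else NULL

  records <- vector("list", train$n_repetitions)
  for (r in seq_len(train$n_repetitions)) {
    rep_seed <- derive_seed(train$seed, "rep", r)
    ctrl_seed <- derive_seed(control$seed, "control", r)
    nets <- if (control$kind == "shuffle_series") {
      lapply(seq_along(runs), function(i)
        build_temporal_network(
          shuffle_series(runs[[i]], mode = control$series_shuffle_mode,
                         seed = derive_seed(ctrl_seed, "series", i)),
          spec = spec))
    } else {
      lapply(seq_along(base_nets), function(i)
        shuffle_windows(base_nets[[i]],
                        seed = derive_seed(ctrl_seed, "win", i)))
    }
    split <- stratified_split(y, train$split_fraction,
                              derive_seed(rep_seed, "split"))
    nf <- normalize_for_split(nets, split$train)
    model <- train_once(nf$tensors[split$train], y[split$train], config,
                        train, seed = derive_seed(rep_seed, "train"))
    metrics <- evaluate_model(model, nf$tensors[split$test], y[split$test])
    records[[r]] <- list(repetition = r, seed = rep_seed,
                         control_seed = ctrl_seed,
                         train_idx = split$train, test_idx = split$test,
                         model = model, normalizer = nf$normalizer,
                         metrics = metrics)
  }
  out <- structure(list(records = records, metrics = metrics_report(records),
                        normalize = "per_repetition"),
                   class = "repetition_run")
  attr(out, "control") <- control
  out
}
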