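# Temporal brain network construction: nuisance regression, zero-phase
# band-pass filtering, sliding-window Pearson correlation, and per-edge
# Z-normalization fitted on training data only.

#' ROI time-series container
#'
#' @param values Numeric matrix, one row per ROI, one column per sample.
#' @param tr Repetition time (seconds per sample).
#' @param roi_ids Optional character vector of ROI identifiers.
#' @return An object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(values, tr, roi_ids = NULL) {
  values <- as.matrix(values)
  if (anyNA(values)) stop_config("ROI time series contains missing values")
  if (ncol(values) < 2) stop_config("ROI time series needs at least 2 samples")
  if (!is.numeric(tr) || tr <= 0) stop_config("tr must be positive")
  roi_ids <- roi_ids %||% paste0("roi", seq_len(nrow(values)) - 1L)
  if (length(roi_ids) != nrow(values))
    stop_config("roi_ids length must match the number of rows")
  structure(list(values = unname(values), tr = tr,
                 roi_ids = as.character(roi_ids)),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat("ROI time series:", nrow(x$values), "ROIs x", ncol(x$values),
      "samples, tr =", x$tr, "s\n")
  invisible(x)
}

#' Sliding-window specification
#'
#' Windows of `window_seconds` advanced by `window_seconds - overlap_seconds`;
#' sample counts are derived from the repetition time at use. Defaults follow
#' the common 30 s window with 7.5 s overlap.
#'
#' @param window_seconds Window length in seconds.
#' @param overlap_seconds Overlap between consecutive windows in seconds.
#' @return A `window_spec` object.
#' @export
window_spec <- function(window_seconds = 30, overlap_seconds = 7.5) {
  if (overlap_seconds < 0 || overlap_seconds >= window_seconds)
    stop_config("overlap must satisfy 0 <= overlap < window")
  structure(list(window_seconds = window_seconds,
                 overlap_seconds = overlap_seconds),
            class = "window_spec")
}

window_samples <- function(spec, tr) {
  w <- as.integer(round(spec$window_seconds / tr))
  if (w < 3) stop_config("window of ", spec$window_seconds,
                         " s is under 3 samples at tr = ", tr)
  w
}

step_samples <- function(spec, tr) {
  w <- window_samples(spec, tr)
  s <- w - as.integer(round(spec$overlap_seconds / tr))
  if (s < 1) stop_config("window step is below 1 sample")
  s
}

#' Regress nuisance signals out of every ROI series
#'
#' Per-ROI ordinary least squares on an intercept plus the given regressor
#' columns (e.g. motion parameters); returns the residual series. Collinear
#' regressor columns are dropped with a warning.
#'
#' @param series A [roi_timeseries].
#' @param regressors Numeric matrix with one row per sample, or `NULL` for
#'   intercept-only regression (mean centering).
#' @return A [roi_timeseries] of residuals, orthogonal to every regressor.
#' @export
regress_nuisance <- function(series, regressors = NULL) {
  stopifnot(inherits(series, "roi_timeseries"))
  l <- ncol(series$values)
  if (!is.null(regressors) && NROW(regressors) != l)
    stop_config("regressors have ", NROW(regressors), " rows; expected ", l)
  x <- cbind(intercept = rep(1, l), regressors)
  if (ncol(x) >= l) stop_config("more regressors than samples")
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    keep <- sort(qx$pivot[seq_len(qx$rank)])
    warning("dropping ", ncol(x) - qx$rank,
            " collinear nuisance regressor column(s)", call. = FALSE)
    qx <- qr(x[, keep, drop = FALSE])
  }
  resid <- qr.resid(qx, t(series$values))
  roi_timeseries(t(resid), tr = series$tr, roi_ids = series$roi_ids)
}

#' Zero-phase band-pass filter of every ROI series
#'
#' Order-4 Butterworth band-pass applied forward and backward
#' ([signal::filtfilt]) so features are not shifted in time; the DC component
#' falls outside any positive passband and is removed.
#'
#' @param series A [roi_timeseries].
#' @param low_hz,high_hz Passband edges in Hz; defaults 0.01-0.08 Hz, the
#'   conventional BOLD fluctuation band.
#' @param order Butterworth filter order.
#' @return Filtered [roi_timeseries] of the same dimensions.
#' @export
bandpass <- function(series, low_hz = 0.01, high_hz = 0.08, order = 4L) {
  stopifnot(inherits(series, "roi_timeseries"))
  nyquist <- 1 / (2 * series$tr)
  if (low_hz <= 0 || low_hz >= high_hz)
    stop_config("need 0 < low_hz < high_hz")
  if (high_hz >= nyquist)
    stop_config("high_hz = ", high_hz, " Hz is at or above the Nyquist ",
                "frequency ", nyquist, " Hz for tr = ", series$tr, " s")
  filt <- signal::butter(order, c(low_hz, high_hz) / nyquist, type = "pass")
  # demean first: the passband excludes DC, and removing the mean up front
  # keeps the forward-backward pass free of step transients at the edges
  filtered <- t(apply(series$values, 1L, function(row)
    signal::filtfilt(filt, row - mean(row))))
  roi_timeseries(filtered, tr = series$tr, roi_ids = series$roi_ids)
}

#' Plan sliding-window boundaries
#'
#' @param n_samples Run length in samples.
#' @param spec A [window_spec].
#' @param tr Repetition time in seconds.
#' @return Integer matrix with columns `start` and `end`: 0-based, half-open
#'   sample windows `[start, end)`, starting at 0 and advancing by
#'   `window - overlap` samples; a trailing partial window is discarded.
#' @examples
#' plan_windows(125, window_spec(30, 7.5), tr = 1.5)
#' @export
plan_windows <- function(n_samples, spec, tr) {
  w <- window_samples(spec, tr)
  s <- step_samples(spec, tr)
  if (n_samples < w)
    stop_config("run of ", n_samples, " samples is shorter than the ",
                w, "-sample window")
  starts <- seq.int(0L, n_samples - w, by = s)
  cbind(start = as.integer(starts), end = as.integer(starts + w))
}

#' Pearson correlation matrix of one window
#'
#' @param series A [roi_timeseries].
#' @param window Length-2 vector `(start, end)`, 0-based half-open.
#' @return Symmetric `R` x `R` matrix with entries in `[-1, 1]` and diagonal
#'   0 (self-correlation carries no information and is removed before
#'   normalization). ROIs with zero variance inside the window get zero
#'   correlations, with a warning.
#' @export
window_correlation <- function(series, window) {
  stopifnot(inherits(series, "roi_timeseries"))
  start <- window[[1]]; end <- window[[2]]
  if (end - start < 3) stop_config("window must span at least 3 samples")
  seg <- series$values[, (start + 1L):end, drop = FALSE]
  sds <- apply(seg, 1L, stats::sd)
  flat <- sds < 1e-12
  mat <- matrix(0, nrow(seg), nrow(seg))
  if (any(!flat)) {
    cc <- stats::cor(t(seg[!flat, , drop = FALSE]))
    mat[!flat, !flat] <- cc
  }
  if (any(flat))
    warning(sum(flat), " ROI(s) with zero variance in window [", start, ",",
            end, "); correlations set to 0", call. = FALSE)
  mat[mat > 1] <- 1
  mat[mat < -1] <- -1
  diag(mat) <- 0
  mat <- (mat + t(mat)) / 2
  mat
}

#' Build the temporal brain network of a run
#'
#' Stacks the windowed Pearson correlation matrices along a third axis in
#' temporal order.
#'
#' @param series A [roi_timeseries].
#' @param spec A [window_spec].
#' @return A `temporal_network`: list with `tensor` (`R` x `R` x `T` array),
#'   `normalization` (`"raw"`), and `window_starts` (0-based).
#' @export
build_temporal_network <- function(series, spec = window_spec()) {
  wins <- plan_windows(ncol(series$values), spec, series$tr)
  r <- nrow(series$values)
  tensor <- array(0, dim = c(r, r, nrow(wins)))
  for (k in seq_len(nrow(wins)))
    tensor[, , k] <- window_correlation(series, wins[k, ])
  temporal_network(tensor, normalization = "raw",
                   window_starts = wins[, "start"])
}

#' Temporal network container
#' @param tensor `R` x `R` x `T` numeric array.
#' @param normalization `"raw"` or `"znormalized"`.
#' @param window_starts 0-based start sample of each window.
#' @return A `temporal_network` object.
#' @export
temporal_network <- function(tensor,
                             normalization = c("raw", "znormalized"),
                             window_starts = NULL) {
  normalization <- match.arg(normalization)
  d <- dim(tensor)
  if (length(d) != 3 || d[1] != d[2])
    stop_config("tensor must be R x R x T")
  window_starts <- window_starts %||% (seq_len(d[3]) - 1L)
  structure(list(tensor = tensor, normalization = normalization,
                 window_starts = as.integer(window_starts)),
            class = "temporal_network")
}

#' @export
print.temporal_network <- function(x, ...) {
  d <- dim(x$tensor)
  cat("Temporal network:", d[1], "x", d[2], "x", d[3],
      paste0("(", x$normalization, ")"), "\n")
  invisible(x)
}

#' Fit a per-edge Z-normalizer on a training pool of networks
#'
#' Computes, for every edge `(i, j)`, the mean and standard deviation of its
#' correlation values across all training networks and all windows
#' (population moments, so renormalizing the training pool itself gives
#' exactly mean 0 and sd 1 per edge). The diagonal is excluded; after
#' normalization a value of 0 represents that edge's average connectivity,
#' which is what makes 0 a neutral masking value downstream. Edges with zero
#' variance pass through as 0 with a warning.
#'
#' @param networks List of `temporal_network`s (training set only; test
#'   statistics must never enter the fit).
#' @return An `edge_normalizer` with `mean` and `sd` matrices.
#' @export
fit_normalizer <- function(networks) {
  if (length(networks) < 2) stop_config("need at least 2 training networks")
  stopifnot(all(vapply(networks, inherits, logical(1), "temporal_network")))
  r <- dim(networks[[1]]$tensor)[1]
  n <- 0
  s1 <- matrix(0, r, r)
  s2 <- matrix(0, r, r)
  for (net in networks) {
    tt <- dim(net$tensor)[3]
    for (k in seq_len(tt)) {
      slice <- net$tensor[, , k]
      s1 <- s1 + slice
      s2 <- s2 + slice^2
    }
    n <- n + tt
  }
  mu <- s1 / n
  var <- pmax(s2 / n - mu^2, 0)
  sd <- sqrt(var)
  zero <- sd < 1e-12
  diag(zero) <- TRUE
  if (any(zero[upper.tri(zero)]))
    warning(sum(zero[upper.tri(zero)]),
            " edge(s) with zero variance in the training pool; ",
            "they will pass through as 0", call. = FALSE)
  structure(list(mean = mu, sd = sd, zero = zero, n = n),
            class = "edge_normalizer")
}

#' Apply a fitted per-edge normalizer to a network
#'
#' @param net A `temporal_network`.
#' @param normalizer An `edge_normalizer` from [fit_normalizer()].
#' @return A `temporal_network` with `normalization = "znormalized"`;
#'   zero-variance edges and the diagonal are 0.
#' @export
apply_normalizer <- function(net, normalizer) {
  stopifnot(inherits(net, "temporal_network"),
            inherits(normalizer, "edge_normalizer"))
  d <- dim(net$tensor)
  if (any(d[1:2] != dim(normalizer$mean)))
    stop_config("network and normalizer dimensions differ")
  sd_safe <- ifelse(normalizer$zero, 1, normalizer$sd)
  out <- array(0, dim = d)
  for (k in seq_len(d[3])) {
    z <- (net$tensor[, , k] - normalizer$mean) / sd_safe
    z[normalizer$zero] <- 0
    out[, , k] <- z
  }
  temporal_network(out, normalization = "znormalized",
                   window_starts = net$window_starts)
}
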