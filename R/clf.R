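# Temporal-convolution classifier: one convolutional layer whose filter spans
# all region pairs and slides only along the time axis, global max-pooling
# over time, and a two-hidden-layer MLP head. Forward, backward and the Adam
# optimizer are implemented as BLAS-backed matrix operations: for filter
# length tau the K = T - tau + 1 temporal positions are unrolled into a
# K x (R*R*tau) design matrix so the convolution is a single matrix product.

#' Model architecture configuration
#'
#' @param n_rois Number of ROIs `R`; the filter spans all `R` x `R` pairs.
#' @param tau Temporal filter length (windows); `tau = 1` makes the model
#'   exactly invariant to window order, `tau > 1` lets it use inter-window
#'   structure. Conventional choices: 4 for modality, 8 for content/combined.
#' @param channels Number of convolution output channels `C`.
#' @param hidden Sizes of the two MLP hidden layers.
#' @param n_classes Number of output classes (2 or 4 here).
#' @param position_bias If `TRUE`, the convolution bias is a full `K` x `C`
#'   matrix indexed by temporal position (this breaks the `tau = 1`
#'   order-invariance and exists for fidelity experiments); default is the
#'   standard per-channel bias broadcast over positions.
#' @return A `model_config` object.
#' @export
model_config <- function(n_rois, tau = 4L, channels = 128L,
                         hidden = c(64L, 32L), n_classes = 2L,
                         position_bias = FALSE) {
  if (tau < 1) stop_config("tau must be at least 1")
  if (channels < 1) stop_config("channels must be at least 1")
  if (length(hidden) != 2) stop_config("hidden must give two layer sizes")
  if (!n_classes %in% c(2L, 3L, 4L) && n_classes < 2)
    stop_config("n_classes must be at least 2")
  structure(list(n_rois = as.integer(n_rois), tau = as.integer(tau),
                 channels = as.integer(channels), hidden = as.integer(hidden),
                 n_classes = as.integer(n_classes),
                 position_bias = isTRUE(position_bias)),
            class = "model_config")
}

#' Training protocol configuration
#'
#' Defaults follow the small-dataset regime: batch size 1, Adam at 1e-4, 20
#' epochs, and 15 retrainings on independent stratified 80/20 splits.
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size Only 1 is supported (each step uses a single sample).
#' @param epochs Number of passes over the training set.
#' @param split_fraction Fraction of samples assigned to training.
#' @param n_repetitions Number of independent retrainings/splits.
#' @param seed Master seed for splits, initialization, and shuffling.
#' @return A `train_config` object.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 1L, epochs = 20L,
                         split_fraction = 0.8, n_repetitions = 15L,
                         seed = 1L) {
  if (split_fraction <= 0 || split_fraction >= 1)
    stop_config("split_fraction must lie in (0, 1)")
  if (epochs < 1) stop_config("epochs must be at least 1")
  if (batch_size != 1L) stop_config("only batch_size = 1 is supported")
  structure(list(learning_rate = learning_rate, batch_size = 1L,
                 epochs = as.integer(epochs), split_fraction = split_fraction,
                 n_repetitions = as.integer(n_repetitions),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Initialize a temporal convolution model
#'
#' Weights use fan-in-scaled uniform initialization
#' `U(-1/sqrt(fan_in), 1/sqrt(fan_in))`; biases start at zero.
#'
#' @param config A [model_config()].
#' @param seed Integer seed.
#' @param n_windows Required when `config$position_bias` is `TRUE` (the bias
#'   matrix needs `K = T - tau + 1`).
#' @return A `temporal_conv_model`.
#' @export
init_model <- function(config, seed = 1L, n_windows = NULL) {
  stopifnot(inherits(config, "model_config"))
  n_feat <- config$n_rois^2 * config$tau
  h <- config$hidden
  uinit <- function(nr, nc, fan_in) {
    lim <- 1 / sqrt(fan_in)
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  with_seed(seed, {
    b <- if (config$position_bias) {
      if (is.null(n_windows))
        stop_config("position_bias models need n_windows at initialization")
      matrix(0, n_windows - config$tau + 1L, config$channels)
    } else {
      numeric(config$channels)
    }
    structure(list(
      W = uinit(n_feat, config$channels, n_feat),
      b = b,
      W1 = uinit(config$channels, h[1], config$channels),
      b1 = numeric(h[1]),
      W2 = uinit(h[1], h[2], h[1]),
      b2 = numeric(h[2]),
      W3 = uinit(h[2], config$n_classes, h[2]),
      b3 = numeric(config$n_classes),
      config = config
    ), class = "temporal_conv_model")
  })
}

#' Number of learnable parameters of a model
#' @param model A `temporal_conv_model`.
#' @return Integer parameter count.
#' @export
n_params <- function(model) {
  sum(vapply(model[c("W", "b", "W1", "b1", "W2", "b2", "W3", "b3")],
             length, integer(1)))
}

as_tensor <- function(x) {
  if (inherits(x, "temporal_network")) x$tensor
  else if (is.array(x) && length(dim(x)) == 3) x
  else stop_config("expected a temporal_network or an R x R x T array")
}

# Unroll an R x R x T tensor into the K x (R*R*tau) design matrix whose row k
# is vec(X[, , k:(k + tau - 1)]).
tensor_to_design <- function(x, tau) {
  d <- dim(x)
  if (d[3] < tau)
    stop_config("tensor has T = ", d[3], " windows but the filter needs tau = ",
                tau)
  k <- d[3] - tau + 1L
  out <- matrix(0, k, d[1] * d[2] * tau)
  for (i in seq_len(k)) out[i, ] <- x[, , i:(i + tau - 1L)]
  out
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

softmax <- function(logits) {
  e <- exp(logits - max(logits))
  e / sum(e)
}

# Forward pass from a precomputed design matrix, retaining the intermediate
# quantities the backward pass needs.
forward_design <- function(model, xmat) {
  k <- nrow(xmat)
  ypre <- xmat %*% model$W
  ypre <- if (is.matrix(model$b)) ypre + model$b
          else ypre + rep(model$b, each = k)
  yact <- relu(ypre)
  kstar <- max.col(t(yact), ties.method = "first")
  z <- yact[cbind(kstar, seq_len(ncol(yact)))]
  h1 <- relu(drop(z %*% model$W1) + model$b1)
  h2 <- relu(drop(h1 %*% model$W2) + model$b2)
  logits <- drop(h2 %*% model$W3) + model$b3
  list(logits = logits, z = z, h1 = h1, h2 = h2, kstar = kstar, k = k)
}

#' Forward pass: logits for one temporal network
#'
#' Computes the convolution over the `K = T - tau + 1` temporal positions,
#' applies ReLU and the per-channel max over positions, then the MLP head
#' (ReLU between layers, none after the last).
#'
#' @param model A `temporal_conv_model`.
#' @param x A `temporal_network` or `R` x `R` x `T` array (normally the
#'   Z-normalized tensor).
#' @return Numeric vector of `n_classes` logits.
#' @export
forward <- function(model, x) {
  xmat <- tensor_to_design(as_tensor(x), model$config$tau)
  forward_design(model, xmat)$logits
}

#' Predicted class of one or more networks
#' @param object A `temporal_conv_model`.
#' @param x_list List of tensors/networks (or a single one).
#' @param ... Unused.
#' @return Integer vector of predicted classes in `0..n_classes-1`; argmax
#'   ties break toward the lowest class index.
#' @export
predict.temporal_conv_model <- function(object, x_list, ...) {
  if (!is.list(x_list) || inherits(x_list, "temporal_network"))
    x_list <- list(x_list)
  vapply(x_list, function(x) which.max(forward(object, x)) - 1L, integer(1))
}

# Cross-entropy loss and parameter gradients for a single sample.
backward_design <- function(model, xmat, y) {
  f <- forward_design(model, xmat)
  p <- softmax(f$logits)
  loss <- -log(max(p[y + 1L], 1e-300))
  dlog <- p
  dlog[y + 1L] <- dlog[y + 1L] - 1
  g <- list()
  g$W3 <- outer(f$h2, dlog)
  g$b3 <- dlog
  dh2 <- drop(model$W3 %*% dlog) * (f$h2 > 0)
  g$W2 <- outer(f$h1, dh2)
  g$b2 <- dh2
  dh1 <- drop(model$W2 %*% dh2) * (f$h1 > 0)
  g$W1 <- outer(f$z, dh1)
  g$b1 <- dh1
  dz <- drop(model$W1 %*% dh1) * (f$z > 0)
  dy <- matrix(0, f$k, length(dz))
  dy[cbind(f$kstar, seq_along(dz))] <- dz
  g$W <- crossprod(xmat, dy)
  g$b <- if (is.matrix(model$b)) dy else colSums(dy)
  list(grads = g, loss = loss)
}

adam_init <- function(model) {
  nms <- c("W", "b", "W1", "b1", "W2", "b2", "W3", "b3")
  list(m = lapply(model[nms], function(p) p * 0),
       v = lapply(model[nms], function(p) p * 0),
       t = 0L)
}

adam_step <- function(model, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(state$m)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    model[[nm]] <- model[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(model = model, state = state)
}

#' Train one model on a fixed training set
#'
#' Batch size 1; the sample order is reshuffled every epoch from the given
#' seed; the final-epoch weights are returned (no early stopping). A class
#' missing from the training set triggers a warning, not an error.
#'
#' @param x_list List of `temporal_network`s or tensors (training inputs).
#' @param y Integer class labels in `0..n_classes-1`.
#' @param config A [model_config()].
#' @param train A [train_config()].
#' @param seed Integer seed (initialization + shuffling); defaults to
#'   `train$seed`.
#' @return A `temporal_conv_model` with attribute `final_loss` (mean
#'   cross-entropy over the last epoch).
#' @export
train_once <- function(x_list, y, config, train = train_config(),
                       seed = train$seed) {
  stopifnot(inherits(config, "model_config"), inherits(train, "train_config"))
  n <- length(x_list)
  if (n == 0) stop_config("empty training set")
  y <- as.integer(y)
  if (any(y < 0 | y >= config$n_classes))
    stop_config("labels must lie in 0..", config$n_classes - 1L)
  missing_cls <- setdiff(seq_len(config$n_classes) - 1L, unique(y))
  if (length(missing_cls))
    warning("class(es) ", paste(missing_cls, collapse = ", "),
            " absent from the training set", call. = FALSE)
  xmats <- lapply(x_list, function(x)
    tensor_to_design(as_tensor(x), config$tau))
  n_windows <- dim(as_tensor(x_list[[1]]))[3]
  model <- init_model(config, seed = derive_seed(seed, "init"),
                      n_windows = n_windows)
  opt <- adam_init(model)
  final_loss <- NA_real_
  with_seed(derive_seed(seed, "shuffle"), {
    for (ep in seq_len(train$epochs)) {
      ord <- sample.int(n)
      losses <- numeric(n)
      for (i in seq_along(ord)) {
        bw <- backward_design(model, xmats[[ord[i]]], y[ord[i]])
        upd <- adam_step(model, bw$grads, opt, train$learning_rate)
        model <- upd$model
        opt <- upd$state
        losses[i] <- bw$loss
      }
      final_loss <- mean(losses)
    }
  })
  attr(model, "final_loss") <- final_loss
  model
}

#' Evaluate a model on a test set
#'
#' Accuracy is the fraction of argmax-correct predictions; precision, recall
#' and F1 are macro-averaged over the classes present in the test set (the
#' design is balanced, where macro and micro agree, but macro stays
#' well-defined on unbalanced sets). A class with no predicted positives gets
#' precision 0; classes absent from the test set are excluded from the macro
#' with a warning.
#'
#' @param model A `temporal_conv_model`.
#' @param x_list List of test inputs.
#' @param y Integer test labels.
#' @return List with `accuracy`, `precision`, `recall`, `f1`, and the
#'   `predictions` vector.
#' @export
evaluate_model <- function(model, x_list, y) {
  if (length(x_list) == 0) stop_config("empty test set")
  pred <- predict(model, x_list)
  classification_metrics(pred, y, model$config$n_classes)
}

#' Accuracy and macro-averaged precision/recall/F1 from predictions
#'
#' @param pred Integer predicted classes.
#' @param y Integer true classes.
#' @param n_classes Total number of classes in the task.
#' @return List with `accuracy`, `precision`, `recall`, `f1` and
#'   `predictions`. Classes absent from `y` are excluded from the macro
#'   averages with a warning; a class never predicted gets precision 0.
#' @export
classification_metrics <- function(pred, y, n_classes) {
  y <- as.integer(y)
  pred <- as.integer(pred)
  all_cls <- seq_len(n_classes) - 1L
  present <- intersect(all_cls, unique(y))
  if (length(present) < length(all_cls))
    warning("class(es) ", paste(setdiff(all_cls, present), collapse = ", "),
            " absent from the test set; excluded from macro averages",
            call. = FALSE)
  per <- vapply(present, function(cls) {
    tp <- sum(pred == cls & y == cls)
    fp <- sum(pred == cls & y != cls)
    fn <- sum(pred != cls & y == cls)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(p, r, f)
  }, numeric(3))
  list(accuracy = mean(pred == y),
       precision = mean(per[1, ]),
       recall = mean(per[2, ]),
       f1 = mean(per[3, ]),
       predictions = pred)
}

# Stratified (or grouped) train/test split. Guarantees at least one training
# and one test sample per class; errors when a class cannot supply both.
stratified_split <- function(y, fraction, seed, groups = NULL) {
  with_seed(seed, {
    if (!is.null(groups)) {
      gids <- unique(groups)
      n_train_g <- max(1L, min(length(gids) - 1L,
                               round(fraction * length(gids))))
      train_g <- sample(gids, n_train_g)
      train_idx <- which(groups %in% train_g)
      test_idx <- setdiff(seq_along(y), train_idx)
    } else {
      counts <- table(y)
      if (any(counts < 2))
        stop_config("stratified split impossible; class counts: ",
                    paste(names(counts), counts, sep = "=", collapse = ", "))
      train_idx <- integer(0)
      for (cls in names(counts)) {
        idx <- sample(which(y == as.integer(cls)))
        n_tr <- max(1L, min(length(idx) - 1L, round(fraction * length(idx))))
        train_idx <- c(train_idx, idx[seq_len(n_tr)])
      }
      train_idx <- sort(train_idx)
      test_idx <- setdiff(seq_along(y), train_idx)
    }
    list(train = train_idx, test = test_idx)
  })
}

# Normalize all networks from moments fitted on the training subset only.
normalize_for_split <- function(networks, train_idx) {
  norm <- fit_normalizer(networks[train_idx])
  list(tensors = lapply(networks, function(nw)
         apply_normalizer(nw, norm)$tensor),
       normalizer = norm)
}

#' Train and evaluate across repeated stratified splits
#'
#' Runs `n_repetitions` independent 80/20 (by default) stratified splits
#' seeded from the master seed; for each repetition the per-edge normalizer
#' is fitted on that repetition's training split only (strict leakage
#' avoidance; `normalize = "global"` reproduces a single whole-dataset fit,
#' `"none"` assumes pre-normalized input). Trained models, normalizers and
#' split indices are retained for downstream Shapley attribution.
#'
#' @param networks List of raw `temporal_network`s (or tensors when
#'   `normalize = "none"`).
#' @param y Integer class labels in `0..n_classes-1`.
#' @param config A [model_config()].
#' @param train A [train_config()].
#' @param normalize `"per_repetition"`, `"global"`, or `"none"`.
#' @param groups Optional grouping vector (e.g. subject ids) for
#'   subject-level splits instead of sample-level stratification.
#' @return A `repetition_run`: list with `records` (per repetition: split
#'   indices, model, normalizer, metrics) and `metrics` (a `metrics_report`
#'   with mean and sd per metric).
#' @export
run_repetitions <- function(networks, y, config, train = train_config(),
                            normalize = c("per_repetition", "global", "none"),
                            groups = NULL) {
  normalize <- match.arg(normalize)
  y <- as.integer(y)
  counts <- table(y)
  if (is.null(groups) && any(counts < 2))
    stop_config("stratification impossible; class counts: ",
                paste(names(counts), counts, sep = "=", collapse = ", "))
  global_norm <- NULL
  if (normalize == "global") {
    global_norm <- fit_normalizer(networks)
    tensors_global <- lapply(networks, function(nw)
      apply_normalizer(nw, global_norm)$tensor)
  }
  records <- vector("list", train$n_repetitions)
  for (r in seq_len(train$n_repetitions)) {
    rep_seed <- derive_seed(train$seed, "rep", r)
    split <- stratified_split(y, train$split_fraction,
                              derive_seed(rep_seed, "split"), groups = groups)
    if (normalize == "per_repetition") {
      nf <- normalize_for_split(networks, split$train)
      tensors <- nf$tensors
      normalizer <- nf$normalizer
    } else if (normalize == "global") {
      tensors <- tensors_global
      normalizer <- global_norm
    } else {
      tensors <- lapply(networks, as_tensor)
      normalizer <- NULL
    }
    model <- train_once(tensors[split$train], y[split$train], config, train,
                        seed = derive_seed(rep_seed, "train"))
    metrics <- evaluate_model(model, tensors[split$test], y[split$test])
    records[[r]] <- list(repetition = r, seed = rep_seed,
                         train_idx = split$train, test_idx = split$test,
                         model = model, normalizer = normalizer,
                         metrics = metrics)
  }
  structure(list(records = records,
                 metrics = metrics_report(records),
                 normalize = normalize),
            class = "repetition_run")
}

#' Aggregate per-repetition metrics into mean and standard deviation
#' @param records List of repetition records (each with a `metrics` element).
#' @return A `metrics_report`: data frame with one row per metric and
#'   columns `mean` and `sd` (sd 0 for a single repetition), plus the
#'   per-repetition values in attribute `per_rep`.
#' @export
metrics_report <- function(records) {
  nms <- c("accuracy", "precision", "recall", "f1")
  per <- vapply(records, function(r) unlist(r$metrics[nms]), numeric(4))
  per <- matrix(per, nrow = 4,
                dimnames = list(nms, paste0("rep", seq_along(records))))
  out <- data.frame(
    metric = nms,
    mean = rowMeans(per),
    sd = apply(per, 1L, function(v) if (length(v) > 1) stats::sd(v) else 0),
    row.names = NULL
  )
  attr(out, "per_rep") <- per
  class(out) <- c("metrics_report", "data.frame")
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  df <- data.frame(metric = x$metric,
                   value = sprintf("%.3f +/- %.3f", x$mean, x$sd))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
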