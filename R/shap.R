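# Shapley-value attribution of classification accuracy to subnetworks:
# coalition masking of the normalized tensor, exact enumeration over all
# 2^|N| coalitions with a shared cache, permutation-sampling approximation
# for large player sets, and aggregation across training repetitions.

#' Zero out all subnetworks outside a coalition
#'
#' For every ROI whose subnetwork is not in `keep`, the corresponding row and
#' column are set to 0 in every time slice. Intended for Z-normalized
#' tensors, where 0 is the per-edge mean connectivity and is therefore a
#' neutral masking value.
#'
#' @param x A `temporal_network` or `R` x `R` x `T` array.
#' @param keep Integer vector of subnetwork labels to leave unmasked (the
#'   coalition); the empty set yields an all-zero tensor.
#' @param parcellation A `parcellation` mapping ROIs to subnetwork labels.
#' @return A masked array of the same dimensions (or `temporal_network` when
#'   one was supplied).
#' @export
mask_coalition <- function(x, keep, parcellation) {
  unknown <- setdiff(as.integer(keep), unique(as.integer(parcellation)))
  if (length(unknown))
    stop_config("unknown subnetwork label(s) ", paste(unknown, collapse = ", "),
                "; known labels: ",
                paste(subnet_labels(parcellation), collapse = ", "))
  tensor <- as_tensor(x)
  drop_rois <- which(!(as.integer(parcellation) %in% as.integer(keep)))
  if (length(drop_rois)) {
    tensor[drop_rois, , ] <- 0
    tensor[, drop_rois, ] <- 0
  }
  if (inherits(x, "temporal_network")) {
    out <- x
    out$tensor <- tensor
    out
  } else {
    tensor
  }
}

#' A cooperative game over subnetwork coalitions
#'
#' Wraps a characteristic function `v` with a coalition cache keyed by
#' bitmask, shared between exact enumeration and permutation sampling so no
#' coalition is ever evaluated twice.
#'
#' @param players Ordered vector of player identifiers (subnetwork labels).
#' @param v Function taking a vector of players (a coalition, possibly
#'   empty) and returning a numeric value.
#' @return A `coalition_game`.
#' @export
coalition_game <- function(players, v) {
  players <- unique(players)
  cache <- new.env(parent = emptyenv())
  structure(list(players = players, v = v, cache = cache),
            class = "coalition_game")
}

# Evaluate (and cache) v on the coalition encoded by a bitmask over the
# player order.
game_value <- function(game, mask) {
  key <- as.character(mask)
  if (!is.null(game$cache[[key]])) return(game$cache[[key]])
  members <- game$players[bitwAnd(mask, bitwShiftL(1L, seq_along(game$players) - 1L)) != 0L]
  val <- game$v(members)
  game$cache[[key]] <- val
  val
}

#' Number of distinct characteristic-function evaluations performed so far
#' @param game A `coalition_game`.
#' @return Integer count of cached coalitions.
#' @export
game_evaluations <- function(game) length(ls(game$cache))

#' The model-accuracy characteristic function
#'
#' `v(S)` is the test accuracy of a fixed trained model when every
#' subnetwork outside `S` is masked to zero in the (normalized) test
#' tensors. The model is trained once on full data; it is never retrained
#' per coalition. `v` of the empty coalition is the accuracy on all-zero
#' input (a constant prediction), which need not equal chance.
#'
#' @param model A trained `temporal_conv_model`.
#' @param tensors List of normalized test tensors.
#' @param y Integer test labels.
#' @param parcellation A `parcellation`.
#' @return A `coalition_game` whose players are the parcellation's
#'   subnetwork labels.
#' @export
accuracy_game <- function(model, tensors, y, parcellation) {
  y <- as.integer(y)
  coalition_game(subnet_labels(parcellation), function(keep) {
    masked <- lapply(tensors, mask_coalition, keep = keep,
                     parcellation = parcellation)
    mean(predict(model, masked) == y)
  })
}

shapley_weights <- function(n) {
  # weight of a coalition of size s (excluding player i): s! (n-s-1)! / n!
  s <- 0:(n - 1)
  exp(lfactorial(s) + lfactorial(n - s - 1) - lfactorial(n))
}

#' Exact Shapley values by full coalition enumeration
#'
#' Evaluates `v` on all `2^|N|` coalitions (cached) and returns each
#' player's average marginal contribution over all orderings. Satisfies the
#' efficiency, symmetry, dummy and additivity axioms by construction.
#'
#' @param game A `coalition_game` with at most 20 players.
#' @return Named numeric vector of Shapley values, in player order.
#' @export
exact_shapley <- function(game) {
  n <- length(game$players)
  if (n > 20)
    stop_config("exact enumeration over 2^", n, " coalitions refused; ",
                "use sampled_shapley()")
  w <- shapley_weights(n)
  vals <- vapply(0:(2^n - 1), function(mask) game_value(game, mask),
                 numeric(1))
  sizes <- vapply(0:(2^n - 1), function(mask) sum(bitwAnd(
    mask, bitwShiftL(1L, 0:(n - 1))) != 0L), numeric(1))
  phi <- numeric(n)
  for (i in seq_len(n)) {
    bit <- bitwShiftL(1L, i - 1L)
    without <- which(bitwAnd(0:(2^n - 1), bit) == 0L)  # 1-based positions
    s_mask <- without - 1L
    phi[i] <- sum(w[sizes[without] + 1] *
                  (vals[without + bit] - vals[without]))
  }
  names(phi) <- as.character(game$players)
  phi
}

#' Monte-Carlo Shapley values by permutation sampling
#'
#' Draws `n_samples` uniform random orderings of the players; for each
#' ordering, every player's marginal contribution over its predecessors is
#' accumulated. The per-player mean is an unbiased estimator of the exact
#' Shapley value. Coalition values are cached across permutations.
#'
#' @param game A `coalition_game`.
#' @param n_samples Number of permutations (default 100).
#' @param seed Integer seed.
#' @return Named numeric vector of estimates with attributes `n_samples` and
#'   `se` (per-player standard error of the mean marginal contribution).
#' @export
sampled_shapley <- function(game, n_samples = 100L, seed = 1L) {
  n <- length(game$players)
  if (n_samples < 1) stop_config("n_samples must be at least 1")
  sums <- numeric(n)
  sq <- numeric(n)
  with_seed(seed, {
    for (s in seq_len(n_samples)) {
      perm <- sample.int(n)
      mask <- 0L
      prev <- game_value(game, mask)
      for (i in perm) {
        mask <- bitwOr(mask, bitwShiftL(1L, i - 1L))
        cur <- game_value(game, mask)
        marg <- cur - prev
        sums[i] <- sums[i] + marg
        sq[i] <- sq[i] + marg^2
        prev <- cur
      }
    }
  })
  phi <- sums / n_samples
  se <- if (n_samples > 1)
    sqrt(pmax(sq / n_samples - phi^2, 0) / (n_samples - 1))
  else rep(NA_real_, n)
  structure(stats::setNames(phi, as.character(game$players)),
            n_samples = n_samples, se = se)
}

#' Shapley attribution across training repetitions
#'
#' For each repetition record from [run_repetitions()], builds the
#' accuracy game from that repetition's trained model and its own test
#' split (normalized with that repetition's normalizer), computes the
#' per-subnetwork Shapley values (exact enumeration by default, permutation
#' sampling for large player sets), and aggregates mean and standard
#' deviation per player across repetitions.
#'
#' @param run A `repetition_run` from [run_repetitions()].
#' @param networks The list of raw `temporal_network`s the run was built on.
#' @param y Integer class labels for all samples.
#' @param parcellation A `parcellation`; its subnetworks are the players.
#' @param method `"exact"` or `"sampled"`.
#' @param n_samples Permutations per repetition when `method = "sampled"`.
#' @param seed Seed for the sampling method.
#' @return A `shapley_report`: data frame with one row per player and
#'   columns `player`, `mean`, `sd`; per-repetition values in attribute
#'   `per_rep`, plus `method`, `n_samples` and per-repetition efficiency
#'   checks (`v_full`, `v_empty`) in attributes.
#' @export
attribute_subnetworks <- function(run, networks, y, parcellation,
                                  method = c("exact", "sampled"),
                                  n_samples = 100L, seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(run, "repetition_run"))
  y <- as.integer(y)
  players <- subnet_labels(parcellation)
  per_rep <- matrix(NA_real_, length(players), length(run$records),
                    dimnames = list(as.character(players), NULL))
  v_full <- v_empty <- numeric(length(run$records))
  for (r in seq_along(run$records)) {
    rec <- run$records[[r]]
    if (is.null(rec$test_idx) || is.null(rec$model))
      stop_config("repetition record ", r, " is missing its split or model")
    tensors <- if (!is.null(rec$normalizer)) {
      lapply(networks[rec$test_idx], function(nw)
        apply_normalizer(nw, rec$normalizer)$tensor)
    } else {
      lapply(networks[rec$test_idx], as_tensor)
    }
    game <- accuracy_game(rec$model, tensors, y[rec$test_idx], parcellation)
    phi <- if (method == "exact") exact_shapley(game)
           else sampled_shapley(game, n_samples = n_samples,
                                seed = derive_seed(seed, "shap", r))
    per_rep[, r] <- phi
    v_full[r] <- game_value(game, 2L^length(players) - 1L)
    v_empty[r] <- game_value(game, 0L)
  }
  out <- data.frame(
    player = players,
    mean = rowMeans(per_rep),
    sd = apply(per_rep, 1L, function(v) if (length(v) > 1) stats::sd(v) else 0),
    row.names = NULL
  )
  attr(out, "per_rep") <- per_rep
  attr(out, "method") <- method
  attr(out, "n_samples") <- if (method == "sampled") n_samples else NA_integer_
  attr(out, "v_full") <- v_full
  attr(out, "v_empty") <- v_empty
  class(out) <- c("shapley_report", "data.frame")
  out
}

#' @export
print.shapley_report <- function(x, ...) {
  cat("Shapley attribution (", attr(x, "method"), " method, ",
      ncol(attr(x, "per_rep")), " repetition(s))\n", sep = "")
  df <- data.frame(subnetwork = x$player,
                   phi = sprintf("%.4f +/- %.4f", x$mean, x$sd))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Bar plot of per-subnetwork Shapley values with sd error bars
#' @param x A `shapley_report`.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the bar midpoints.
#' @export
plot.shapley_report <- function(x, ...) {
  mids <- graphics::barplot(x$mean, names.arg = x$player,
                            ylab = "Shapley value (accuracy)",
                            xlab = "subnetwork",
                            ylim = range(0, x$mean + x$sd, x$mean - x$sd),
                            ...)
  graphics::arrows(mids, x$mean - x$sd, mids, x$mean + x$sd,
                   angle = 90, code = 3, length = 0.04)
  invisible(mids)
}
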