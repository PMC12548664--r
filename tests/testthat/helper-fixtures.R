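# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

# Small planted-effect dataset: 12 ROIs in 3 subnetworks, modality effect in
# subnetwork 0, content order-coded in subnetworks 1 and 2.
tiny_sim_config <- function(seed = 11L) {
  sim_config(n_subjects = 4, n_narratives_per_subject = 8,
             n_rois = 12, n_timepoints = 120, tr = 1.5,
             subnetwork_sizes = c(4L, 4L, 4L),
             modality_effect_subnets = 0L,
             content_effect_subnets = c(1L, 2L),
             modality_effect_size = 0.1, content_effect_size = 0.15,
             seed = seed)
}

tiny_dataset <- function() memo("tiny_dataset", function() {
  make_dataset(tiny_sim_config())
})

tiny_networks <- function() memo("tiny_networks", function() {
  lapply(tiny_dataset()$runs, build_temporal_network)
})

# Stationary multivariate-normal series with a known correlation structure.
stationary_series <- function(n_rois = 4, n_samples = 400, rho = 0.5,
                              tr = 1.5, seed = 5) {
  sigma <- matrix(rho, n_rois, n_rois)
  diag(sigma) <- 1
  ch <- chol(sigma)
  values <- withr::with_seed(seed,
    crossprod(ch, matrix(rnorm(n_rois * n_samples), n_rois, n_samples)))
  roi_timeseries(values, tr = tr)
}

# A model whose MLP is an identity pass-through of the pooled channel, so
# logits[1] equals the max-pooled convolution output Z (for C = 1 channels).
passthrough_model <- function(n_rois, tau, W_value, n_classes = 2) {
  cfg <- model_config(n_rois, tau = tau, channels = 1L, hidden = c(1L, 1L),
                      n_classes = n_classes)
  m <- init_model(cfg, seed = 1)
  m$W <- matrix(W_value, n_rois^2 * tau, 1L)
  m$b <- 0
  m$W1 <- matrix(1, 1, 1); m$b1 <- 0
  m$W2 <- matrix(1, 1, 1); m$b2 <- 0
  m$W3 <- matrix(c(1, rep(0, n_classes - 1)), 1, n_classes); m$b3 <- numeric(n_classes)
  m
}

# Random cooperative game with values drawn i.i.d.; characteristic function
# keyed by sorted coalition members.
random_game <- function(n_players, seed) {
  vals <- withr::with_seed(seed, {
    v <- stats::runif(2^n_players)
    v[1] <- 0
    v
  })
  players <- seq_len(n_players)
  coalition_game(players, function(s) {
    mask <- sum(2^(sort(s) - 1))
    vals[mask + 1]
  })
}

# Independent oracle: Shapley values as the average of marginal
# contributions over ALL |N|! orderings (feasible for |N| <= 5).
permutation_average_shapley <- function(game) {
  n <- length(game$players)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  phi <- numeric(n)
  all_orders <- perms(seq_len(n))
  for (ord in all_orders) {
    prev <- game$v(integer(0))
    members <- integer(0)
    for (i in ord) {
      members <- c(members, game$players[i])
      cur <- game$v(members)
      phi[i] <- phi[i] + (cur - prev)
      prev <- cur
    }
  }
  stats::setNames(phi / length(all_orders), as.character(game$players))
}

# Naive triple-loop evaluation of the temporal convolution + ReLU + max-pool,
# independent of the package's design-matrix path.
naive_conv_pool <- function(x, W4, b) {
  r <- dim(x)[1]; tt <- dim(x)[3]
  tau <- dim(W4)[3]; cc <- dim(W4)[4]
  k_max <- tt - tau + 1
  y <- matrix(0, k_max, cc)
  for (k in seq_len(k_max)) for (c in seq_len(cc)) {
    acc <- 0
    for (i in seq_len(r)) for (j in seq_len(r)) for (p in seq_len(tau))
      acc <- acc + x[i, j, k + p - 1] * W4[i, j, p, c]
    y[k, c] <- max(0, acc + b[c])
  }
  apply(y, 2, max)
}
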