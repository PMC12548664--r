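test_that("forward matches hand evaluation of the convolution sum", {
  # R=1, T=2, tau=1, C=1, W=2, b=0, X=[0.5, -1]: Y = relu([1, -2]) = [1, 0],
  # max-pool Z = 1; the pass-through MLP reports Z in logits[1]
  m <- passthrough_model(1, tau = 1, W_value = 2)
  x <- array(c(0.5, -1), dim = c(1, 1, 2))
  expect_equal(forward(m, x), c(1, 0))

  # zero filter: logits constant over arbitrary inputs
  cfg <- model_config(3, tau = 2, channels = 4, n_classes = 2)
  mz <- init_model(cfg, seed = 2)
  mz$W[] <- 0
  mz$b[] <- 0
  base <- forward(mz, array(0, c(3, 3, 4)))
  for (i in 1:5) {
    x <- array(rnorm(36), c(3, 3, 4))
    expect_identical(forward(mz, x), base)
  }

  # tau = T collapses to a single weighted sum over the whole tensor
  m1 <- passthrough_model(2, tau = 3, W_value = 1)
  x <- array(rnorm(12), c(2, 2, 3))
  expect_equal(forward(m1, x)[1], max(0, sum(x)))

  # T < tau is a shape error naming both
  expect_error(forward(m1, array(0, c(2, 2, 2))), "T = 2.*tau = 3")
})

test_that("convolution equals the naive triple-loop oracle", {
  for (i in 1:12) {
    set.seed(100 + i)
    r <- sample(2:4, 1)
    tt <- sample(2:5, 1)
    tau <- sample(seq_len(tt), 1)
    cc <- sample(1:3, 1)
    cfg <- model_config(r, tau = tau, channels = cc, n_classes = 2)
    m <- init_model(cfg, seed = i)
    m$W <- matrix(rnorm(length(m$W)), nrow(m$W), ncol(m$W))
    m$b <- rnorm(cc)
    x <- array(rnorm(r * r * tt), c(r, r, tt))
    z_pkg <- dfcnet:::forward_design(
      m, dfcnet:::tensor_to_design(x, tau))$z
    w4 <- array(m$W, dim = c(r, r, tau, cc))
    expect_equal(z_pkg, naive_conv_pool(x, w4, m$b), tolerance = 1e-6)
  }
})

test_that("parameter count follows the architecture formula", {
  for (spec in list(c(5, 2, 8, 2), c(3, 1, 4, 4), c(10, 3, 16, 2))) {
    r <- spec[1]; tau <- spec[2]; cc <- spec[3]; ncls <- spec[4]
    m <- init_model(model_config(r, tau, cc, n_classes = ncls), seed = 1)
    expect_equal(n_params(m),
                 r * r * tau * cc + cc + (cc * 64 + 64) +
                   (64 * 32 + 32) + (32 * ncls + ncls))
  }
})

test_that("tau = 1 models are exactly invariant to window order", {
  for (i in 1:10) {
    set.seed(200 + i)
    cfg <- model_config(3, tau = 1, channels = 5, n_classes = 2)
    m <- init_model(cfg, seed = i)
    x <- array(rnorm(45), c(3, 3, 5))
    perm <- sample(5)
    expect_identical(forward(m, x), forward(m, x[, , perm]))
  }
})

test_that("tau > 1 models are order-sensitive (constructive)", {
  # one channel looking at the rise from window k to k+1 of a single edge
  cfg <- model_config(1, tau = 2, channels = 1, hidden = c(1, 1),
                      n_classes = 2)
  m <- passthrough_model(1, tau = 2, W_value = 0)
  m$W <- matrix(c(-1, 1), 2, 1)  # response x[t+1] - x[t]
  x <- array(c(0, 1, 2), c(1, 1, 3))     # increasing: max rise 1
  x_rev <- array(c(2, 1, 0), c(1, 1, 3)) # decreasing: rises negative
  expect_equal(forward(m, x)[1], 1)
  expect_equal(forward(m, x_rev)[1], 0)
  expect_false(identical(forward(m, x), forward(m, x_rev)))
})

test_that("position-dependent bias breaks order invariance when enabled", {
  cfg <- model_config(2, tau = 1, channels = 3, n_classes = 2,
                      position_bias = TRUE)
  m <- init_model(cfg, seed = 3, n_windows = 4)
  expect_true(is.matrix(m$b))
  m$b <- matrix(rnorm(12), 4, 3)
  set.seed(4)
  x <- array(rnorm(16), c(2, 2, 4))
  expect_false(identical(forward(m, x), forward(m, x[, , c(2, 1, 4, 3)])))
})

test_that("training is deterministic and fits a separable planted effect", {
  ds <- tiny_dataset()
  nets <- tiny_networks()
  y <- task_labels(ds, "modality")

  # separability pre-check via a linear probe on the modality block mean
  b0 <- which(as.integer(ds$parcellation) == 0L)
  feats <- t(vapply(nets, function(n)
    vapply(seq_len(dim(n$tensor)[3]), function(k)
      mean(n$tensor[b0, b0, k]), numeric(1)),
    numeric(dim(nets[[1]]$tensor)[3])))
  fit <- suppressWarnings(stats::glm.fit(cbind(1, feats), y,
                                         family = stats::binomial()))
  probe_acc <- mean(as.integer(cbind(1, feats) %*% fit$coefficients > 0) == y)
  expect_gte(probe_acc, 0.95)

  norm <- fit_normalizer(nets)
  tensors <- lapply(nets, function(n) apply_normalizer(n, norm)$tensor)
  cfg <- model_config(12, tau = 4, channels = 8, n_classes = 2)
  tc <- train_config(learning_rate = 1e-3, epochs = 10, n_repetitions = 2,
                     seed = 7)
  m1 <- train_once(tensors, y, cfg, tc, seed = 99)
  m2 <- train_once(tensors, y, cfg, tc, seed = 99)
  expect_identical(attr(m1, "final_loss"), attr(m2, "final_loss"))
  expect_identical(m1$W, m2$W)

  train_acc <- mean(predict(m1, tensors) == y)
  expect_gte(train_acc, 0.95)
})

test_that("training on permuted labels stays at chance on held-out data", {
  nets <- tiny_networks()
  y <- task_labels(tiny_dataset(), "modality")
  y_perm <- withr::with_seed(13, sample(y))
  cfg <- model_config(12, tau = 4, channels = 8, n_classes = 2)
  tc <- train_config(learning_rate = 1e-3, epochs = 8, n_repetitions = 5,
                     seed = 17)
  run <- run_repetitions(nets, y_perm, cfg, tc)
  accs <- attr(run$metrics, "per_rep")["accuracy", ]
  n_test <- length(run$records[[1]]$test_idx)
  # mean across repetitions within 3 sd of the binomial chance level
  se <- sqrt(0.25 / (n_test * length(accs)))
  expect_lt(abs(mean(accs) - 0.5), 3 * se + 1e-9)
})

test_that("classification metrics match hand-computed confusion counts", {
  # all correct
  perfect <- classification_metrics(c(0, 1, 0, 1), c(0, 1, 0, 1), 2)
  expect_equal(unlist(perfect[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))

  # TP=3 FP=1 FN=1 TN=3 for class 1: accuracy .75, macro P = R = F1 = .75
  y <- c(1, 1, 1, 1, 0, 0, 0, 0)
  pred <- c(1, 1, 1, 0, 1, 0, 0, 0)
  m <- classification_metrics(pred, y, 2)
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$f1, 0.75)

  # single-class test set: absent class excluded with warning
  expect_warning(m1 <- classification_metrics(c(1, 1), c(1, 1), 2),
                 "absent")
  expect_equal(m1$recall, 1)
  expect_equal(m1$accuracy, 1)
})

test_that("repetition protocol produces seeded, stratified records", {
  nets <- tiny_networks()
  y <- task_labels(tiny_dataset(), "modality")
  cfg <- model_config(12, tau = 2, channels = 4, n_classes = 2)
  tc <- train_config(learning_rate = 1e-3, epochs = 2, n_repetitions = 3,
                     seed = 23)
  run <- run_repetitions(nets, y, cfg, tc)
  expect_length(run$records, 3)
  for (rec in run$records) {
    expect_setequal(c(rec$train_idx, rec$test_idx), seq_along(y))
    # stratification: both classes in both halves
    expect_setequal(unique(y[rec$train_idx]), c(0, 1))
    expect_setequal(unique(y[rec$test_idx]), c(0, 1))
    # ~80/20 split
    expect_equal(length(rec$train_idx), round(0.8 * length(y)), tolerance = 1)
  }
  # same master seed: identical split index lists
  run2 <- run_repetitions(nets, y, cfg, tc)
  expect_identical(lapply(run$records, `[[`, "train_idx"),
                   lapply(run2$records, `[[`, "train_idx"))
  expect_identical(run$metrics$mean, run2$metrics$mean)

  # single repetition reports sd 0
  tc1 <- train_config(learning_rate = 1e-3, epochs = 1, n_repetitions = 1,
                      seed = 29)
  run1 <- run_repetitions(nets, y, cfg, tc1)
  expect_identical(run1$metrics$sd, rep(0, 4))

  # impossible stratification errors with class counts
  expect_error(run_repetitions(nets[1:3], c(0L, 0L, 1L), cfg, tc),
               "class counts")
})

test_that("normalizer is fitted per repetition on the training split only", {
  nets <- tiny_networks()
  y <- task_labels(tiny_dataset(), "modality")
  cfg <- model_config(12, tau = 2, channels = 4, n_classes = 2)
  tc <- train_config(learning_rate = 1e-3, epochs = 1, n_repetitions = 2,
                     seed = 31)
  run <- run_repetitions(nets, y, cfg, tc, normalize = "per_repetition")
  for (rec in run$records) {
    ref <- fit_normalizer(nets[rec$train_idx])
    expect_equal(rec$normalizer$mean, ref$mean)
    expect_equal(rec$normalizer$sd, ref$sd)
  }
  # global mode: one normalizer over the full pool, shared by repetitions
  rg <- run_repetitions(nets, y, cfg, tc, normalize = "global")
  expect_identical(rg$records[[1]]$normalizer$mean,
                   rg$records[[2]]$normalizer$mean)
  expect_equal(rg$records[[1]]$normalizer$mean, fit_normalizer(nets)$mean)
})
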