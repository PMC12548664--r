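test_that("parcellation assigns contiguous blocks and validates sizes", {
  p <- make_parcellation(6, c(2, 2, 2))
  expect_identical(as.integer(p), c(0L, 0L, 1L, 1L, 2L, 2L))

  p7 <- make_parcellation(100, c(14, 14, 14, 14, 14, 15, 15))
  expect_identical(subnet_labels(p7), 0:6)
  expect_identical(as.integer(table(as.integer(p7))),
                   c(14L, 14L, 14L, 14L, 14L, 15L, 15L))

  expect_error(make_parcellation(5, c(2, 2)), "sum to 4")
})

test_that("state covariance encodes effects in the planted blocks", {
  cfg0 <- sim_config(n_subjects = 1, n_narratives_per_subject = 4,
                     n_rois = 9, subnetwork_sizes = c(3, 3, 3),
                     modality_effect_subnets = 0L,
                     content_effect_subnets = c(1L, 2L),
                     modality_effect_size = 0, content_effect_size = 0)
  parc <- make_parcellation(9, c(3, 3, 3))

  # zero effects: identical baseline across all labels and states
  s_ref <- build_state_covariance(parc, 0, 0, 0L, cfg0)
  for (m in 0:1) for (co in 0:1) for (st in 0:(cfg0$n_states - 1))
    expect_equal(build_state_covariance(parc, m, co, st, cfg0), s_ref,
                 ignore_attr = TRUE)
  expect_equal(unname(diag(s_ref)), rep(1, 9))
  expect_equal(s_ref[1, 5], cfg0$baseline_corr)

  # signed modality increment: off-diagonal differs by 2 * 0.3 between labels
  cfg <- cfg0
  cfg$modality_effect_size <- 0.3
  s1 <- build_state_covariance(parc, 1, 0, 0L, cfg)
  s0 <- build_state_covariance(parc, 0, 0, 0L, cfg)
  expect_equal(s1[1, 2] - s0[1, 2], 0.6, tolerance = 1e-12)
  expect_equal(s1[5, 6], s0[5, 6])  # outside the modality block: untouched

  # positive definiteness across the full label/state grid
  cfgc <- cfg0
  cfgc$modality_effect_size <- 0.1
  cfgc$content_effect_size <- 0.2
  for (m in 0:1) for (co in 0:1) for (st in 0:(cfgc$n_states - 1)) {
    sig <- build_state_covariance(parc, m, co, st, cfgc)
    expect_gt(min(eigen(sig, symmetric = TRUE, only.values = TRUE)$values), 0)
    expect_equal(sig, t(sig))
  }
})

test_that("content increments visit blocks in a content-specific order", {
  cfg <- sim_config(n_subjects = 1, n_narratives_per_subject = 4,
                    n_rois = 9, subnetwork_sizes = c(3, 3, 3),
                    modality_effect_subnets = 0L,
                    content_effect_subnets = c(1L, 2L),
                    modality_effect_size = 0, content_effect_size = 0.2,
                    n_states = 4L)
  parc <- make_parcellation(9, c(3, 3, 3))
  block_level <- function(content, st, block_first_roi) {
    s <- build_state_covariance(parc, 0, content, st, cfg)
    s[block_first_roi, block_first_roi + 1]
  }
  # content 0 raises block 1 in even states; content 1 in odd states
  lev_c0 <- vapply(0:3, function(st) block_level(0, st, 4L), numeric(1))
  lev_c1 <- vapply(0:3, function(st) block_level(1, st, 4L), numeric(1))
  expect_equal(lev_c0, cfg$baseline_corr + c(0.2, 0, 0.2, 0))
  expect_equal(lev_c1, cfg$baseline_corr + c(0, 0.2, 0, 0.2))
  # the per-state multiset over states is content-invariant (order coding)
  expect_equal(sort(lev_c0), sort(lev_c1))
})

test_that("excessive increments are shrunk with a warning, staying PD", {
  cfg <- sim_config(n_subjects = 1, n_narratives_per_subject = 4,
                    n_rois = 30, subnetwork_sizes = c(10, 10, 10),
                    modality_effect_subnets = 0L,
                    content_effect_subnets = c(1L, 2L),
                    modality_effect_size = 0.4, content_effect_size = 0)
  parc <- make_parcellation(30, c(10, 10, 10))
  expect_warning(sig <- build_state_covariance(parc, 0, 0, 0L, cfg),
                 "shrunk")
  expect_lt(attr(sig, "shrinkage"), 1)
  expect_gt(min(eigen(sig, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("simulate_run is deterministic and matches its covariance", {
  cfg <- tiny_sim_config()
  r1 <- simulate_run(0, 0, 1, 0, cfg)
  r2 <- simulate_run(0, 0, 1, 0, cfg)
  expect_identical(r1$values, r2$values)
  expect_identical(dim(r1$values), c(12L, 120L))
  # different narrative id gives a different draw
  r3 <- simulate_run(0, 1, 1, 0, cfg)
  expect_false(identical(r1$values, r3$values))

  # sample-covariance oracle: no noise, no AR, long segments
  cfg_long <- sim_config(n_subjects = 1, n_narratives_per_subject = 4,
                         n_rois = 6, n_timepoints = 4000,
                         subnetwork_sizes = c(2, 2, 2),
                         modality_effect_subnets = 0L,
                         content_effect_subnets = c(1L, 2L),
                         modality_effect_size = 0.1,
                         content_effect_size = 0.15,
                         n_states = 2L, noise_sd = 0, ar_coeff = 0, seed = 3)
  run <- simulate_run(0, 0, 1, 0, cfg_long)
  parc <- make_parcellation(6, c(2, 2, 2))
  seg_len <- 2000
  for (st in 0:1) {
    seg <- run$values[, st * seg_len + seq_len(seg_len)]
    emp <- tcrossprod(seg) / seg_len
    expected <- build_state_covariance(parc, 1, 0, st, cfg_long)
    expect_lt(max(abs(emp - expected)), 4 * sqrt(2 / seg_len))
  }
})

test_that("timepoint remainder is absorbed by the final segment", {
  expect_identical(dfcnet:::state_segments(10L, 3L), c(3L, 3L, 4L))
  expect_identical(dfcnet:::state_segments(12L, 4L), rep(3L, 4L))
  cfg <- tiny_sim_config()
  cfg$n_timepoints <- 121L
  run <- simulate_run(0, 0, 0, 0, cfg)
  expect_identical(ncol(run$values), 121L)
})

test_that("make_dataset balances the 2x2 design and is reproducible", {
  ds <- tiny_dataset()
  expect_length(ds$runs, 32L)
  cells <- table(ds$labels$modality, ds$labels$content)
  expect_true(all(cells == 8L))

  bad <- tiny_sim_config()
  bad$n_narratives_per_subject <- 6L
  expect_error(make_dataset(bad), "divisible by 4")

  # byte-wise determinism of the full dataset
  ds2 <- make_dataset(tiny_sim_config())
  expect_identical(serialize(ds, NULL), serialize(ds2, NULL))
})

test_that("content is decodable from window order only when planted", {
  # linear probe on window-ordered block-contrast features
  probe_accuracy <- function(content_effect) {
    cfg <- sim_config(n_subjects = 6, n_narratives_per_subject = 8,
                      n_rois = 12, subnetwork_sizes = c(4, 4, 4),
                      modality_effect_subnets = 0L,
                      content_effect_subnets = c(1L, 2L),
                      modality_effect_size = 0,
                      content_effect_size = content_effect, seed = 21)
    ds <- make_dataset(cfg)
    nets <- lapply(ds$runs, build_temporal_network)
    b1 <- which(as.integer(ds$parcellation) == 1L)
    b2 <- which(as.integer(ds$parcellation) == 2L)
    feats <- t(vapply(nets, function(n) {
      vapply(seq_len(dim(n$tensor)[3]), function(k)
        mean(n$tensor[b1, b1, k]) - mean(n$tensor[b2, b2, k]), numeric(1))
    }, numeric(dim(nets[[1]]$tensor)[3])))
    y <- task_labels(ds, "content")
    train <- withr::with_seed(31, seq_along(y) %in% sample(seq_along(y), 24))
    fit <- suppressWarnings(stats::glm.fit(cbind(1, feats[train, ]), y[train],
                                           family = stats::binomial()))
    pred <- as.integer(cbind(1, feats[!train, ]) %*% fit$coefficients > 0)
    mean(pred == y[!train])
  }
  acc_null <- probe_accuracy(0)
  acc_planted <- probe_accuracy(0.2)
  # chance within 3 binomial sd for the null, strong decodability when planted
  n_test <- 24
  expect_lt(abs(acc_null - 0.5), 3 * sqrt(0.25 / n_test))
  expect_gt(acc_planted, 0.8)
})
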