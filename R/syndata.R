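# Synthetic dataset generator: covariance block-model emulation of BOLD runs
# with planted, subnetwork-localized class effects. Modality information is
# carried by the within-block covariance of every latent state (decodable from
# any single window); content information is carried only by the ORDER in
# which latent connectivity states visit the content-effect subnetworks, so
# destroying window order destroys content decodability by construction.

#' Simulation configuration for the synthetic narrative dataset
#'
#' Defines the study conditions the generator emulates: a cohort of subjects
#' each exposed to a balanced 2x2 design of narratives (modality audio/movie x
#' content airport/restaurant), with region-of-interest (ROI) signals drawn
#' from latent-state multivariate normal covariance blocks. Defaults mirror a
#' cohort of 31 subjects, 16 three-minute narratives each, 100 ROIs at a
#' repetition time of 1.5 s, partitioned into 7 subnetworks.
#'
#' @param n_subjects Number of subjects.
#' @param n_narratives_per_subject Narratives per subject; must be divisible
#'   by 4 so the 2x2 modality-by-content design balances within subject.
#' @param n_rois Number of ROIs (`R`).
#' @param n_timepoints Samples per run (default 120 = 3 min at `tr` 1.5 s).
#' @param tr Repetition time, seconds per sample.
#' @param subnetwork_sizes Integer vector of subnetwork sizes summing to
#'   `n_rois`; subnetworks are contiguous ROI blocks labelled `0..K-1`.
#' @param modality_effect_subnets Subnetwork labels whose within-block
#'   covariance is raised (modality 1) or lowered (modality 0) by
#'   `modality_effect_size` in every latent state.
#' @param content_effect_subnets Two or more subnetwork labels visited in a
#'   content-specific order across latent states; with fewer than two labels
#'   no order information exists and content is undecodable.
#' @param modality_effect_size,content_effect_size Covariance increments
#'   (dimensionless, added to off-diagonal entries inside effect blocks).
#'   The modality increment is signed by label, so keeping it at or below
#'   `baseline_corr` leaves every state covariance positive-definite
#'   without shrinkage; content increments are always positive.
#' @param n_states Number of latent connectivity states per run; the run is
#'   divided into `n_states` equal segments (the last absorbs any remainder).
#' @param noise_sd Standard deviation of white measurement noise.
#' @param ar_coeff Order-1 autoregressive smoothing coefficient in `[0, 1)`.
#' @param baseline_corr Uniform off-diagonal covariance of the baseline
#'   (effect-free) state; keeps matrices well-conditioned at `n_rois = 100`.
#' @param seed Master seed for the generator.
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_subjects = 2, n_narratives_per_subject = 4,
#'                   n_rois = 12, subnetwork_sizes = c(4, 4, 4))
#' @export
sim_config <- function(n_subjects = 31L,
                       n_narratives_per_subject = 16L,
                       n_rois = 100L,
                       n_timepoints = 120L,
                       tr = 1.5,
                       subnetwork_sizes = c(14L, 14L, 14L, 14L, 14L, 15L, 15L),
                       modality_effect_subnets = 0L,
                       content_effect_subnets = c(5L, 6L),
                       modality_effect_size = 0.1,
                       content_effect_size = 0.15,
                       n_states = 4L,
                       noise_sd = 0.5,
                       ar_coeff = 0.3,
                       baseline_corr = 0.1,
                       seed = 1L) {
  if (sum(subnetwork_sizes) != n_rois)
    stop_config("subnetwork_sizes sum to ", sum(subnetwork_sizes),
                " but n_rois is ", n_rois)
  if (any(subnetwork_sizes <= 0)) stop_config("subnetwork sizes must be positive")
  if (modality_effect_size < 0 || content_effect_size < 0)
    stop_config("effect sizes must be non-negative")
  if (ar_coeff < 0 || ar_coeff >= 1) stop_config("ar_coeff must lie in [0, 1)")
  if (noise_sd < 0) stop_config("noise_sd must be non-negative")
  if (n_states < 1) stop_config("n_states must be at least 1")
  if (n_timepoints < n_states) stop_config("n_timepoints must be >= n_states")
  labels <- seq_along(subnetwork_sizes) - 1L
  bad_m <- setdiff(modality_effect_subnets, labels)
  bad_c <- setdiff(content_effect_subnets, labels)
  if (length(bad_m) || length(bad_c))
    stop_config("effect subnetworks ", paste(c(bad_m, bad_c), collapse = ", "),
                " are not among declared labels ", paste(labels, collapse = ", "))
  structure(list(
    n_subjects = as.integer(n_subjects),
    n_narratives_per_subject = as.integer(n_narratives_per_subject),
    n_rois = as.integer(n_rois),
    n_timepoints = as.integer(n_timepoints),
    tr = tr,
    subnetwork_sizes = as.integer(subnetwork_sizes),
    modality_effect_subnets = as.integer(modality_effect_subnets),
    content_effect_subnets = as.integer(content_effect_subnets),
    modality_effect_size = modality_effect_size,
    content_effect_size = content_effect_size,
    n_states = as.integer(n_states),
    noise_sd = noise_sd,
    ar_coeff = ar_coeff,
    baseline_corr = baseline_corr,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Assign ROIs to subnetworks in contiguous blocks
#'
#' The parcellation defines the "players" of the Shapley attribution: each ROI
#' belongs to exactly one subnetwork, labelled `0..K-1` in block order.
#'
#' @param n_rois Number of ROIs.
#' @param subnetwork_sizes Positive integers summing to `n_rois`.
#' @return A `parcellation`: an integer vector of length `n_rois` with the
#'   subnetwork label of each ROI.
#' @examples
#' make_parcellation(6, c(2, 2, 2))
#' @export
make_parcellation <- function(n_rois, subnetwork_sizes) {
  if (any(subnetwork_sizes <= 0)) stop_config("subnetwork sizes must be positive")
  if (sum(subnetwork_sizes) != n_rois)
    stop_config("subnetwork_sizes sum to ", sum(subnetwork_sizes),
                " but n_rois is ", n_rois)
  labels <- rep(seq_along(subnetwork_sizes) - 1L, times = subnetwork_sizes)
  structure(as.integer(labels), class = "parcellation",
            sizes = as.integer(subnetwork_sizes))
}

#' @export
print.parcellation <- function(x, ...) {
  sizes <- attr(x, "sizes")
  cat("Parcellation of", length(x), "ROIs into", length(sizes),
      "subnetworks (sizes:", paste(sizes, collapse = ", "), ")\n")
  invisible(x)
}

#' Subnetwork labels declared by a parcellation
#' @param parcellation A `parcellation` object.
#' @return Sorted integer vector of distinct subnetwork labels.
#' @export
subnet_labels <- function(parcellation) sort(unique(as.integer(parcellation)))

# ROI indices (1-based) belonging to any of the given subnetwork labels.
rois_in_subnets <- function(parcellation, labels) {
  which(as.integer(parcellation) %in% as.integer(labels))
}

# Which content-effect block receives the content increment in a given state:
# content 0 cycles through the blocks in declared order, content 1 starts the
# cycle one block later, so the two contents visit the same multiset of
# blocks in a different order.
content_block_for_state <- function(config, content, state_index) {
  blocks <- config$content_effect_subnets
  m <- length(blocks)
  if (m == 0L) return(integer(0))
  blocks[((state_index + content) %% m) + 1L]
}

#' Construct the covariance matrix of one latent connectivity state
#'
#' The baseline is unit variance with a weak uniform off-diagonal correlation.
#' Modality adds a signed increment (`+e` for modality 1, `-e` for modality 0)
#' to off-diagonal entries inside every modality-effect block, identically in
#' all states. Content adds its increment to exactly one content-effect block
#' per state, chosen by a content-specific cyclic ordering of states, so the
#' marginal distribution of a single state over states is content-invariant
#' while the state SEQUENCE is not.
#'
#' If the increments would break positive-definiteness the increments are
#' halved (repeatedly) with a warning; the shrinkage factor is recorded in the
#' `"shrinkage"` attribute of the result.
#'
#' @param parcellation A `parcellation` covering `config$n_rois` ROIs.
#' @param modality,content Class labels in `{0, 1}`.
#' @param state_index Latent state index in `0..n_states-1`.
#' @param config A `sim_config`.
#' @return A symmetric positive-definite `n_rois` x `n_rois` matrix with
#'   attribute `shrinkage` (1 when no shrinkage was needed).
#' @export
build_state_covariance <- function(parcellation, modality, content,
                                   state_index, config) {
  stopifnot(inherits(config, "sim_config"))
  if (state_index < 0 || state_index >= config$n_states)
    stop_config("state_index ", state_index, " outside 0..", config$n_states - 1L)
  r <- config$n_rois
  base <- matrix(config$baseline_corr, r, r)
  diag(base) <- 1

  mod_sign <- if (modality == 1) 1 else -1
  content_block <- content_block_for_state(config, content, state_index)

  add_block <- function(mat, labels, eps) {
    for (lab in labels) {
      idx <- rois_in_subnets(parcellation, lab)
      blk <- matrix(eps, length(idx), length(idx))
      diag(blk) <- 0
      mat[idx, idx] <- mat[idx, idx] + blk
    }
    mat
  }

  shrink <- 1
  repeat {
    sigma <- base
    if (config$modality_effect_size > 0)
      sigma <- add_block(sigma, config$modality_effect_subnets,
                         mod_sign * config$modality_effect_size * shrink)
    if (config$content_effect_size > 0 && length(content_block))
      sigma <- add_block(sigma, content_block,
                         config$content_effect_size * shrink)
    if (min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values) > 1e-8)
      break
    shrink <- shrink / 2
    if (shrink < 1e-4)
      stop_config("covariance not positive-definite even after shrinking increments")
  }
  if (shrink < 1)
    warning("effect increments shrunk by factor ", shrink,
            " to keep the state covariance positive-definite", call. = FALSE)
  attr(sigma, "shrinkage") <- shrink
  sigma
}

# Segment lengths: n_states equal segments, remainder absorbed by the last.
state_segments <- function(n_timepoints, n_states) {
  base <- n_timepoints %/% n_states
  lens <- rep(base, n_states)
  lens[n_states] <- lens[n_states] + n_timepoints - base * n_states
  lens
}

#' Simulate one run's ROI time-series matrix
#'
#' Concatenates `n_states` segments; within each segment, innovations are
#' drawn from a zero-mean multivariate normal with that state's covariance,
#' passed through an order-1 autoregressive filter (applied across the whole
#' run, so the signal is continuous at state boundaries), and white
#' measurement noise is added. Deterministic given
#' `(seed, subject_id, narrative_id)`.
#'
#' @param subject_id,narrative_id Integer identifiers.
#' @param modality,content Class labels in `{0, 1}`.
#' @param config A `sim_config`.
#' @param seed Master seed; defaults to `config$seed`.
#' @return A [roi_timeseries] with `config$n_rois` rows and
#'   `config$n_timepoints` columns.
#' @export
simulate_run <- function(subject_id, narrative_id, modality, content,
                         config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!modality %in% c(0, 1) || !content %in% c(0, 1))
    stop_config("modality and content labels must be 0 or 1")
  parc <- make_parcellation(config$n_rois, config$subnetwork_sizes)
  lens <- state_segments(config$n_timepoints, config$n_states)
  run_seed <- derive_seed(seed, "run", subject_id, narrative_id)

  values <- with_seed(run_seed, {
    innov <- matrix(0, config$n_rois, config$n_timepoints)
    pos <- 0L
    for (s in seq_len(config$n_states)) {
      sigma <- build_state_covariance(parc, modality, content, s - 1L, config)
      ch <- chol(sigma)
      z <- matrix(stats::rnorm(config$n_rois * lens[s]), config$n_rois, lens[s])
      innov[, pos + seq_len(lens[s])] <- crossprod(ch, z)
      pos <- pos + lens[s]
    }
    x <- innov
    if (config$ar_coeff > 0) {
      for (t in 2:ncol(x)) x[, t] <- config$ar_coeff * x[, t - 1L] + innov[, t]
    }
    if (config$noise_sd > 0)
      x <- x + matrix(stats::rnorm(length(x), sd = config$noise_sd),
                      nrow(x), ncol(x))
    x
  })
  roi_timeseries(values, tr = config$tr,
                 roi_ids = paste0("roi", seq_len(config$n_rois) - 1L))
}

#' Generate a full synthetic dataset with balanced 2x2 labels
#'
#' Each subject contributes `n_narratives_per_subject` runs cycling through
#' the four (modality, content) cells, so the design is balanced within every
#' subject. The planted ground truth (effect subnetworks and sizes) is
#' recorded alongside.
#'
#' @param config A `sim_config`; `n_narratives_per_subject` must be divisible
#'   by 4.
#' @return A `synthetic_dataset`: list with `runs` (list of
#'   [roi_timeseries]), `labels` (data frame with subject_id, narrative_id,
#'   modality, content), `parcellation`, `ground_truth`, and `config`.
#' @examples
#' ds <- make_dataset(sim_config(n_subjects = 2, n_narratives_per_subject = 4,
#'                               n_rois = 9, n_timepoints = 40,
#'                               subnetwork_sizes = c(3, 3, 3),
#'                               content_effect_subnets = c(1L, 2L)))
#' table(ds$labels$modality, ds$labels$content)
#' @export
make_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_narratives_per_subject %% 4L != 0L)
    stop_config("n_narratives_per_subject (", config$n_narratives_per_subject,
                ") must be divisible by 4 to balance the 2x2 design")
  parc <- make_parcellation(config$n_rois, config$subnetwork_sizes)
  labels <- do.call(rbind, lapply(seq_len(config$n_subjects) - 1L, function(s) {
    j <- seq_len(config$n_narratives_per_subject) - 1L
    data.frame(subject_id = s, narrative_id = j,
               modality = (j %% 4L) %/% 2L, content = j %% 2L)
  }))
  runs <- vector("list", nrow(labels))
  for (i in seq_len(nrow(labels))) {
    runs[[i]] <- simulate_run(labels$subject_id[i], labels$narrative_id[i],
                              labels$modality[i], labels$content[i], config)
  }
  structure(list(
    runs = runs,
    labels = labels,
    parcellation = parc,
    ground_truth = list(
      modality_effect_subnets = config$modality_effect_subnets,
      content_effect_subnets = config$content_effect_subnets,
      modality_effect_size = config$modality_effect_size,
      content_effect_size = config$content_effect_size
    ),
    config = config
  ), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic narrative dataset:", length(x$runs), "runs,",
      x$config$n_rois, "ROIs x", x$config$n_timepoints, "timepoints\n")
  cat("Label balance (modality x content):\n")
  print(table(modality = x$labels$modality, content = x$labels$content))
  invisible(x)
}

#' Class labels for one of the three classification tasks
#'
#' @param dataset A `synthetic_dataset` (or any list with a `labels` data
#'   frame holding `modality` and `content` columns).
#' @param task `"modality"`, `"content"`, or `"combined"` (4 classes coded
#'   `2 * modality + content`).
#' @return Integer vector of class labels in `0..n_classes-1`.
#' @export
task_labels <- function(dataset, task = c("modality", "content", "combined")) {
  task <- match.arg(task)
  lab <- dataset$labels
  switch(task,
    modality = as.integer(lab$modality),
    content = as.integer(lab$content),
    combined = as.integer(2L * lab$modality + lab$content)
  )
}
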