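# Orchestration: one configuration object ties simulation, network
# construction, training, Shapley attribution and controls into the three
# classification tasks (modality, content, combined), with a single master
# seed fanning out deterministically to every stage and optional
# content-addressed caching of stage outputs.

#' Experiment configuration
#'
#' @param task `"modality"`, `"content"`, or `"combined"`; determines the
#'   number of classes (2, 2, 4) and the default filter length `tau`
#'   (4, 8, 8).
#' @param sim A [sim_config()] describing the synthetic dataset, or a path
#'   to a dataset directory readable by [read_dataset()].
#' @param window A [window_spec()].
#' @param model A [model_config()], or `NULL` to derive one from the task
#'   defaults (`channels` then defaults to 128).
#' @param train A [train_config()].
#' @param attribution List with `method` (`"exact"`/`"sampled"`/`"none"`)
#'   and `n_samples`.
#' @param controls List of [control_spec()]s to run after the main task.
#' @param master_seed Single integer every stage seed derives from.
#' @param channels,tau Convenience overrides applied when `model` is `NULL`.
#' @param normalize Normalization scope passed to [run_repetitions()]:
#'   `"per_repetition"` (default; normalizer fitted on each repetition's
#'   training split) or `"global"` (single whole-dataset fit).
#' @return An `experiment_config`.
#' @export
experiment_config <- function(task = c("modality", "content", "combined"),
                              sim = sim_config(),
                              window = window_spec(),
                              model = NULL,
                              train = train_config(),
                              attribution = list(method = "exact",
                                                 n_samples = 100L),
                              controls = list(),
                              master_seed = 1L,
                              channels = 128L,
                              tau = NULL,
                              normalize = c("per_repetition", "global")) {
  task <- match.arg(task)
  normalize <- match.arg(normalize)
  n_classes <- if (task == "combined") 4L else 2L
  tau <- tau %||% if (task == "modality") 4L else 8L
  if (is.null(model)) {
    n_rois <- if (inherits(sim, "sim_config")) sim$n_rois else NA_integer_
    model <- if (!is.na(n_rois))
      model_config(n_rois, tau = tau, channels = channels,
                   n_classes = n_classes)
    else NULL
  }
  if (!is.null(model) && model$n_classes != n_classes)
    stop_config("task '", task, "' needs ", n_classes,
                " classes but model has ", model$n_classes)
  structure(list(task = task, sim = sim, window = window, model = model,
                 train = train, attribution = attribution,
                 controls = controls, master_seed = as.integer(master_seed),
                 normalize = normalize),
            class = "experiment_config")
}

cache_fetch <- function(cache_dir, key, compute) {
  if (is.null(cache_dir)) return(compute())
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  f <- file.path(cache_dir, paste0(key, ".rds"))
  if (file.exists(f)) return(readRDS(f))
  val <- compute()
  saveRDS(val, f)
  val
}

#' Run the full pipeline for one experiment configuration
#'
#' Simulate (or ingest) the dataset, build temporal networks, train and
#' evaluate across repetitions (normalizer fitted per repetition's training
#' split), attribute accuracy to subnetworks with Shapley values, and run
#' the requested controls. All stage seeds derive from
#' `config$master_seed`; rerunning an identical configuration reproduces
#' every number, and with a `cache_dir` the simulation and network stages
#' are reused via content-addressed keys.
#'
#' @param config An [experiment_config()].
#' @param cache_dir Optional directory for stage caches.
#' @param verbose Print per-stage progress lines.
#' @return A `run_report`: list with `config`, `dataset` summary info,
#'   `metrics` (a `metrics_report`), `shapley` (a `shapley_report` or
#'   `NULL`), `controls` (named list of control `repetition_run`s), and
#'   `seeds`.
#' @export
run_pipeline <- function(config, cache_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (verbose) message("[dfcnet] ", ...)
  t0 <- proc.time()[["elapsed"]]

  sim_seed <- derive_seed(config$master_seed, "sim")
  train_seed <- derive_seed(config$master_seed, "train")
  shap_seed <- derive_seed(config$master_seed, "shap")

  dataset <- if (inherits(config$sim, "sim_config")) {
    sim <- config$sim
    sim$seed <- sim_seed
    cache_fetch(cache_dir, paste0("sim-", content_hash(sim)),
                function() make_dataset(sim))
  } else {
    read_dataset(config$sim)
  }
  say("dataset: ", length(dataset$runs), " runs (",
      round(proc.time()[["elapsed"]] - t0, 1), "s)")

  networks <- cache_fetch(
    cache_dir,
    paste0("nets-", content_hash(list(
      if (inherits(config$sim, "sim_config")) config$sim else dataset$labels,
      sim_seed, config$window))),
    function() lapply(dataset$runs, build_temporal_network,
                      spec = config$window))
  say("networks: T = ", dim(networks[[1]]$tensor)[3])

  model_cfg <- config$model %||%
    model_config(dim(networks[[1]]$tensor)[1],
                 tau = if (config$task == "modality") 4L else 8L,
                 n_classes = if (config$task == "combined") 4L else 2L)
  tt <- dim(networks[[1]]$tensor)[3]
  if (model_cfg$tau > tt) {
    say("tau ", model_cfg$tau, " exceeds T = ", tt, "; clamping to T")
    model_cfg$tau <- tt
  }
  y <- task_labels(dataset, config$task)
  tr_cfg <- config$train
  tr_cfg$seed <- train_seed

  run <- run_repetitions(networks, y, model_cfg, tr_cfg,
                         normalize = config$normalize)
  say("metrics: accuracy ", sprintf("%.3f", run$metrics$mean[1]))

  shapley <- NULL
  if (!identical(config$attribution$method, "none")) {
    shapley <- attribute_subnetworks(
      run, networks, y, dataset$parcellation,
      method = config$attribution$method,
      n_samples = config$attribution$n_samples %||% 100L,
      seed = shap_seed)
    say("shapley: top subnetwork ", shapley$player[which.max(shapley$mean)])
  }

  controls <- list()
  for (ctrl in config$controls) {
    cs <- ctrl
    cs$seed <- derive_seed(config$master_seed, "ctrl", ctrl$kind, ctrl$seed)
    controls[[ctrl$kind]] <-
      run_control(dataset, y, cs, spec = config$window,
                  config = model_cfg, train = tr_cfg)
    say("control ", ctrl$kind, ": accuracy ",
        sprintf("%.3f", controls[[ctrl$kind]]$metrics$mean[1]))
  }

  structure(list(config = config,
                 n_runs = length(dataset$runs),
                 n_windows = tt,
                 model_config = model_cfg,
                 run = run,
                 metrics = run$metrics,
                 shapley = shapley,
                 controls = controls,
                 seeds = list(master = config$master_seed, sim = sim_seed,
                              train = train_seed, shap = shap_seed),
                 elapsed_s = proc.time()[["elapsed"]] - t0),
            class = "run_report")
}

#' Summary tables for a run report
#'
#' @param object A `run_report`.
#' @param ... Unused.
#' @return List with `metrics` (data frame: one row per metric, columns for
#'   the main task and each control) and `shapley` (per-player mean/sd data
#'   frame in declared parcellation order, or `NULL`).
#' @export
summary.run_report <- function(object, ...) {
  tab <- data.frame(metric = object$metrics$metric,
                    mean = object$metrics$mean,
                    sd = object$metrics$sd)
  names(tab)[2:3] <- paste0(object$config$task, c("_mean", "_sd"))
  for (nm in names(object$controls)) {
    cm <- object$controls[[nm]]$metrics
    tab[[paste0(nm, "_mean")]] <- cm$mean
    tab[[paste0(nm, "_sd")]] <- cm$sd
  }
  list(metrics = tab,
       shapley = if (!is.null(object$shapley))
         as.data.frame(object$shapley) else NULL)
}

#' @export
print.run_report <- function(x, ...) {
  cat("dfcnet run --", x$config$task, "task,", x$n_runs, "runs, T =",
      x$n_windows, "\n\n")
  print(x$metrics)
  for (nm in names(x$controls)) {
    cat("\ncontrol:", nm, "\n")
    print(x$controls[[nm]]$metrics)
  }
  if (!is.null(x$shapley)) {
    cat("\n")
    print(x$shapley)
  }
  invisible(x)
}

#' Write a machine-readable JSON report
#' @param report A `run_report`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_report_json <- function(report, path) {
  s <- summary(report)
  out <- list(task = report$config$task,
              n_runs = report$n_runs,
              n_windows = report$n_windows,
              seeds = report$seeds,
              metrics = s$metrics,
              shapley = s$shapley)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
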