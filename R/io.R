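# External interfaces: ROI series as tab-delimited text with a JSON sidecar
# per run, parcellation lookup as two-column TSV, dataset directories with a
# manifest, and a native serialized store for temporal-network tensors.

#' Write one run's ROI series as TSV plus JSON sidecar
#'
#' The TSV has one row per ROI, a first column of ROI identifiers, and a
#' header row of sample times in seconds. The sidecar (same path with
#' `.json` appended) records tr and any metadata given.
#'
#' @param series A [roi_timeseries].
#' @param path Output TSV path.
#' @param metadata Named list (e.g. subject_id, narrative_id, modality,
#'   content) stored in the sidecar.
#' @return Invisibly, `path`.
#' @export
write_run <- function(series, path, metadata = list()) {
  stopifnot(inherits(series, "roi_timeseries"))
  times <- (seq_len(ncol(series$values)) - 1L) * series$tr
  df <- data.frame(roi_id = series$roi_ids,
                   series$values, check.names = FALSE)
  colnames(df) <- c("roi_id", format(times, trim = TRUE, digits = 15))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- c(list(tr = series$tr), metadata)
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read one run written by [write_run()]
#' @param path TSV path (sidecar expected at `<path>.json`).
#' @return A [roi_timeseries] with attribute `metadata`.
#' @export
read_run <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  values <- as.matrix(df[, -1, drop = FALSE])
  out <- roi_timeseries(values, tr = side$tr, roi_ids = df$roi_id)
  attr(out, "metadata") <- side[setdiff(names(side), "tr")]
  out
}

#' Write a parcellation lookup table (roi_id TAB subnetwork_label)
#' @param parcellation A `parcellation`.
#' @param path Output TSV path.
#' @param roi_ids Optional ROI identifier column.
#' @return Invisibly, `path`.
#' @export
write_parcellation <- function(parcellation, path, roi_ids = NULL) {
  roi_ids <- roi_ids %||% paste0("roi", seq_along(parcellation) - 1L)
  utils::write.table(
    data.frame(roi_id = roi_ids, subnetwork = as.integer(parcellation)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a parcellation lookup table
#' @param path TSV path with columns roi_id and subnetwork.
#' @return A `parcellation` (labels in file order).
#' @export
read_parcellation <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  labels <- as.integer(df$subnetwork)
  structure(labels, class = "parcellation",
            sizes = as.integer(table(labels)[as.character(sort(unique(labels)))]))
}

#' Write a synthetic dataset to a directory
#'
#' One TSV + JSON sidecar per run, a parcellation TSV, and a JSON manifest
#' with labels and ground truth. Everything is plain text and round-trips
#' through [read_dataset()] losslessly up to float formatting (values are
#' written with full precision).
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(dataset$runs))
  for (i in seq_along(dataset$runs)) {
    lab <- dataset$labels[i, ]
    files[i] <- sprintf("sub%03d_narr%03d.tsv", lab$subject_id,
                        lab$narrative_id)
    write_run(dataset$runs[[i]], file.path(dir, files[i]),
              metadata = as.list(lab))
  }
  write_parcellation(dataset$parcellation, file.path(dir, "parcellation.tsv"))
  manifest <- list(files = files,
                   labels = dataset$labels,
                   ground_truth = dataset$ground_truth)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#' @param dir Dataset directory.
#' @return A `synthetic_dataset` (without the originating `sim_config`).
#' @export
read_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  runs <- lapply(manifest$files, function(f) read_run(file.path(dir, f)))
  labels <- as.data.frame(manifest$labels)
  structure(list(runs = runs,
                 labels = labels,
                 parcellation = read_parcellation(
                   file.path(dir, "parcellation.tsv")),
                 ground_truth = manifest$ground_truth,
                 config = NULL),
            class = "synthetic_dataset")
}

#' Save temporal networks to a serialized store
#'
#' One native-serialization file per run plus a JSON index recording window
#' starts and normalization state.
#'
#' @param networks List of `temporal_network`s.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
save_networks <- function(networks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  index <- lapply(seq_along(networks), function(i) {
    f <- sprintf("net%04d.rds", i)
    saveRDS(networks[[i]], file.path(dir, f))
    list(file = f, normalization = networks[[i]]$normalization,
         window_starts = networks[[i]]$window_starts)
  })
  jsonlite::write_json(index, file.path(dir, "index.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load temporal networks saved by [save_networks()]
#' @param dir Store directory.
#' @return List of `temporal_network`s in index order.
#' @export
load_networks <- function(dir) {
  index <- jsonlite::read_json(file.path(dir, "index.json"),
                               simplifyVector = TRUE)
  lapply(index$file, function(f) readRDS(file.path(dir, f)))
}
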