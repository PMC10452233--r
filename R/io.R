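# Plain-text I/O: cohorts as one delimited matrix per subject plus a JSON
# sidecar; feature tables and metric tables as TSV.

#' Write a cohort as delimited text plus JSON sidecar
#'
#' One `<id>_data.tsv` per subject, channels x (samples * epochs), epochs
#' concatenated along columns; a single `cohort.json` sidecar holds
#' dimensions, sampling rate, epoch times, labels, seeds and ground truth.
#'
#' @param cohort A `cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(fs = cohort$config$fs, n_rois = cohort$config$n_rois,
               dipoles_per_roi = cohort$config$dipoles_per_roi,
               band = cohort$config$band, subjects = list())
  for (s in cohort$subjects) {
    d <- dim(s$epochs$data)
    flat <- matrix(s$epochs$data, nrow = d[1])
    f <- file.path(dir, paste0(s$id, "_data.tsv"))
    utils::write.table(format(flat, digits = 10), f, sep = "\t",
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
    meta$subjects[[s$id]] <- list(
      group = s$group, seed = s$seed, dim = d,
      epoch_times = s$epochs$epoch_times,
      ground_truth = s$ground_truth, file = basename(f))
  }
  jsonlite::write_json(meta, file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return List with `subjects` (each: `id`, `group`, `seed`, `epochs`,
#'   `ground_truth`), `labels`, `fs`.
#' @export
read_cohort <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "cohort.json"),
                              simplifyVector = TRUE)
  subjects <- list()
  labels <- character(0)
  for (id in names(meta$subjects)) {
    m <- meta$subjects[[id]]
    flat <- as.matrix(utils::read.table(file.path(dir, m$file), sep = "\t"))
    dat <- array(as.numeric(flat), dim = m$dim)
    gt <- m$ground_truth
    if (!is.null(gt)) gt <- as.data.frame(gt)
    subjects[[id]] <- list(
      id = id, group = m$group, seed = m$seed,
      epochs = sensor_epochs(dat, meta$fs, epoch_times = m$epoch_times),
      ground_truth = gt)
    labels[id] <- m$group
  }
  list(subjects = subjects, labels = unname(labels), fs = meta$fs)
}

#' Write a subjects x features table
#'
#' @param features Matrix with one row per subject.
#' @param labels Group label per subject.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, labels, path) {
  df <- data.frame(subject = rownames(features) %||% seq_len(nrow(features)),
                   group = labels, features, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a features table written by [write_features()]
#'
#' @param path TSV path.
#' @return List with `features` (matrix), `labels`, `subjects`.
#' @export
read_features <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  list(features = as.matrix(df[, -(1:2), drop = FALSE]),
       labels = df$group, subjects = df$subject)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
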