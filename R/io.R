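#' Read and write parcel time series
#'
#' Delimited text (TSV): a header row of parcel IDs, one row per volume.
#' The round trip `write_timeseries()` then `read_timeseries()` preserves
#' values to better than 1e-12 relative. Ragged rows, missing cells and
#' duplicate parcel IDs are explicit errors.
#'
#' @param path File path.
#' @param tr_s Sampling interval to attach (seconds).
#' @param run_id,task Metadata to attach (see [parcel_ts()]).
#' @return `read_timeseries()`: a [parcel_ts()]; `write_timeseries()`: the
#'   path, invisibly.
#' @export
read_timeseries <- function(path, tr_s = 2, run_id = basename(path),
                            task = c("task", "rest")) {
  if (!file.exists(path)) stop("no such file: ", path)
  fields <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(fields)) != 1L) {
    stop("ragged rows in ", path, " (rows ",
         paste(utils::head(which(fields != fields[1L]), 3L), collapse = ", "),
         ")")
  }
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df)
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing/non-numeric cell in %s at row %d, column '%s'",
                 path, bad[1L], colnames(m)[bad[2L]]))
  }
  parcel_ts(m, tr_s = tr_s, parcel_ids = colnames(m), run_id = run_id,
            task = match.arg(task))
}

#' @rdname read_timeseries
#' @param ts A [parcel_ts()].
#' @export
write_timeseries <- function(ts, path) {
  df <- as.data.frame(format(ts$data, digits = 17, trim = TRUE,
                             scientific = TRUE))
  names(df) <- ts$parcel_ids
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read trial onsets from a BIDS-style events table
#'
#' Expects tab-separated columns `onset` (seconds) and optionally
#' `duration`; other columns are ignored.
#'
#' @param path File path.
#' @return Numeric vector of onsets, sorted.
#' @export
read_events <- function(path) {
  df <- utils::read.delim(path)
  if (!"onset" %in% names(df)) stop("events file lacks an `onset` column")
  sort(as.numeric(df$onset))
}

#' Read a confound table
#'
#' Tab-separated with the nine named columns consumed by
#' [build_nuisance()]; validation of the column set happens there.
#'
#' @param path File path.
#' @return data.frame of confound signals.
#' @export
read_confounds <- function(path) {
  utils::read.delim(path)
}

#' Read and write atlas labels
#'
#' Tab-separated lookup with columns `parcel_id` and `network`.
#'
#' @param path File path.
#' @return `read_atlas()`: data.frame with `parcel_id`, `network`.
#' @export
read_atlas <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  if (!all(c("parcel_id", "network") %in% names(df))) {
    stop("atlas file needs columns `parcel_id` and `network`")
  }
  df[c("parcel_id", "network")]
}

#' @rdname read_atlas
#' @param atlas data.frame with `parcel_id`, `network`.
#' @export
write_atlas <- function(atlas, path) {
  utils::write.table(atlas, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a connectivity matrix as TSV
#'
#' Parcel-ID header row and first column; values on the Fisher-z scale.
#'
#' @param mat A [conn_matrix()].
#' @param path File path.
#' @export
write_conn_matrix <- function(mat, path) {
  df <- data.frame(parcel_id = mat$parcel_ids,
                   format(mat$z, digits = 17, trim = TRUE),
                   check.names = FALSE)
  names(df) <- c("parcel_id", mat$parcel_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a subject tree written by [write_cohort()]
#'
#' @param dir Cohort root directory.
#' @param tr_s Sampling interval (seconds).
#' @return A list shaped like [simulate_cohort()] output minus the ground
#'   truth: `atlas` plus `subjects`, each with `rest_run` and `task_runs`
#'   (every run holding `ts`, `confounds`, and `onsets` for task runs).
#' @export
read_cohort <- function(dir, tr_s = 2) {
  atlas <- read_atlas(file.path(dir, "atlas_labels.tsv"))
  sub_dirs <- sort(list.dirs(dir, recursive = FALSE))
  sub_dirs <- sub_dirs[grepl("^sub-", basename(sub_dirs))]
  if (length(sub_dirs) == 0L) stop("no sub-* directories under ", dir)
  subjects <- lapply(sub_dirs, function(sd) {
    sid <- basename(sd)
    func <- file.path(sd, "ses-1", "func")
    ts_files <- sort(list.files(func, pattern = "_timeseries\\.tsv$",
                                full.names = TRUE))
    runs <- lapply(ts_files, function(f) {
      stem <- sub("_timeseries\\.tsv$", "", f)
      rid <- sub(sprintf("^%s_", sid), "", basename(stem))
      is_rest <- grepl("task-rest", rid)
      run <- list(
        ts = read_timeseries(f, tr_s = tr_s, run_id = rid,
                             task = if (is_rest) "rest" else "task"),
        confounds = read_confounds(paste0(stem, "_confounds.tsv"))
      )
      ev <- paste0(stem, "_events.tsv")
      if (file.exists(ev)) run$onsets <- read_events(ev)
      run
    })
    is_rest <- vapply(runs, function(r) r$ts$task == "rest", TRUE)
    if (sum(is_rest) != 1L) stop(sid, ": expected exactly one rest run")
    list(subject_id = sid, rest_run = runs[[which(is_rest)]],
         task_runs = runs[!is_rest])
  })
  list(atlas = atlas, subjects = subjects)
}
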