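#' Parcel time series
#'
#' Container for a single run of parcel-level BOLD signal: a volumes x parcels
#' numeric matrix plus its sampling interval. This is the unit that every
#' stage of the pipeline (filtering, task removal, scrubbing, connectivity)
#' transforms.
#'
#' @param data Numeric matrix, volumes x parcels. No missing values.
#' @param tr_s Sampling interval (repetition time) in seconds.
#' @param parcel_ids Character vector of unique parcel identifiers; defaults
#'   to the column names of `data`, or `"p001"`, `"p002"`, ... when absent.
#' @param run_id Identifier for the run (used in filenames and messages).
#' @param task Either `"rest"` or `"task"`.
#'
#' @return An object of class `parcel_ts`: a list with elements `data`,
#'   `tr_s`, `parcel_ids`, `run_id`, `task`.
#' @examples
#' ts <- parcel_ts(matrix(rnorm(40), 10, 4), tr_s = 2)
#' dim(ts$data)
#' @export
parcel_ts <- function(data, tr_s, parcel_ids = NULL, run_id = "run-1",
                      task = c("task", "rest")) {
  task <- match.arg(task)
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("`data` must be a numeric matrix")
  if (nrow(data) < 2L) stop("a parcel time series needs at least 2 volumes")
  if (anyNA(data)) stop("`data` contains missing values")
  if (!is.numeric(tr_s) || length(tr_s) != 1L || tr_s <= 0) {
    stop("`tr_s` must be a single positive number (seconds)")
  }
  if (is.null(parcel_ids)) {
    parcel_ids <- colnames(data)
    if (is.null(parcel_ids)) parcel_ids <- sprintf("p%03d", seq_len(ncol(data)))
  }
  parcel_ids <- as.character(parcel_ids)
  if (length(parcel_ids) != ncol(data)) {
    stop("length of `parcel_ids` must equal the number of parcels (columns)")
  }
  if (anyDuplicated(parcel_ids)) stop("`parcel_ids` must be unique")
  colnames(data) <- parcel_ids
  structure(
    list(data = data, tr_s = tr_s, parcel_ids = parcel_ids,
         run_id = run_id, task = task),
    class = "parcel_ts"
  )
}

#' @export
print.parcel_ts <- function(x, ...) {
  cat(sprintf("<parcel_ts> %s (%s): %d volumes x %d parcels, TR %g s\n",
              x$run_id, x$task, nrow(x$data), ncol(x$data), x$tr_s))
  invisible(x)
}

#' @export
dim.parcel_ts <- function(x) dim(x$data)

# replace the data block, keeping metadata
ts_with_data <- function(ts, data) {
  out <- ts
  colnames(data) <- ts$parcel_ids
  out$data <- data
  out
}

as_parcel_ts <- function(x, tr_s = 2) {
  if (inherits(x, "parcel_ts")) x else parcel_ts(x, tr_s = tr_s)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. All stochastic code in the package funnels through
# this so results are reproducible run-to-run and independent of call order.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
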