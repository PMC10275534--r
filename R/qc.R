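#' Framewise displacement
#'
#' Per-volume head-motion summary in the Power convention: the sum of
#' absolute volume-to-volume differences of the six rigid-body parameters,
#' with rotations (radians) converted to arc length on a 50-mm sphere.
#' The first volume has FD 0 by convention.
#'
#' @param motion Matrix or data.frame, volumes x 6: three translations (mm)
#'   then three rotations (radians).
#' @param radius_mm Sphere radius for the rotation conversion (default 50).
#' @return Numeric vector of FD values (mm), one per volume.
#' @export
framewise_displacement <- function(motion, radius_mm = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) {
    stop("`motion` must have 6 columns: 3 translations (mm), 3 rotations (rad)")
  }
  d <- abs(diff(motion))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    rowSums(d[, 4:6, drop = FALSE]) * radius_mm
  c(0, fd)
}

#' DVARS for parcel time series
#'
#' Per-volume intensity-change index: the root-mean-square over parcels of
#' the backward temporal difference, expressed as a percentage of the grand
#' mean absolute signal level. The first volume is 0 by convention. The
#' percentage is invariant to rescaling the whole dataset.
#'
#' @param ts A [parcel_ts()] (or matrix).
#' @return Numeric vector of DVARS values (percent), one per volume.
#' @export
dvars <- function(ts) {
  x <- if (inherits(ts, "parcel_ts")) ts$data else as.matrix(ts)
  level <- mean(abs(x))
  if (level == 0) stop("DVARS undefined: grand mean absolute signal is zero")
  rms <- sqrt(rowMeans(diff(x)^2))
  c(0, 100 * rms / level)
}

#' QC trace for a run
#'
#' Convenience bundle of [framewise_displacement()] and [dvars()] plus the
#' retain mask at the given thresholds.
#'
#' @param motion Volumes x 6 motion parameters.
#' @param ts A [parcel_ts()] (the raw series QC is judged on).
#' @param fd_thresh FD threshold, mm (default 0.5).
#' @param dvars_thresh DVARS threshold, percent (default 0.5).
#' @return A list of class `qc_trace`: `fd_mm`, `dvars_pct`, `mask`
#'   (TRUE = retain), `fd_thresh`, `dvars_thresh`.
#' @export
qc_trace <- function(motion, ts, fd_thresh = 0.5, dvars_thresh = 0.5) {
  fd <- framewise_displacement(motion)
  dv <- dvars(ts)
  if (length(fd) != length(dv)) stop("motion and time series lengths differ")
  structure(
    list(fd_mm = fd, dvars_pct = dv,
         mask = fd <= fd_thresh & dv <= dvars_thresh,
         fd_thresh = fd_thresh, dvars_thresh = dvars_thresh),
    class = "qc_trace"
  )
}

#' Scrub contaminated volumes
#'
#' Removes volumes whose framewise displacement or DVARS exceeds its
#' threshold, concatenating the surviving volumes in order. If fewer than
#' `min_retained_frac` of the volumes survive, the run is flagged
#' "insufficient data" (mirroring subject/run exclusion after scrubbing);
#' flagged runs should be dropped by the caller.
#'
#' @param ts A [parcel_ts()] to censor (may be a filtered or residualized
#'   version of the series the QC trace was computed on).
#' @param qc A [qc_trace()] of matching length.
#' @param fd_thresh,dvars_thresh Censoring thresholds (mm, percent).
#' @param min_retained_frac Minimum fraction of volumes that must survive.
#' @return A list: `ts` (scrubbed [parcel_ts()]), `mask` (TRUE = retained),
#'   `retained_frac`, `flagged` (logical).
#' @export
scrub <- function(ts, qc, fd_thresh = 0.5, dvars_thresh = 0.5,
                  min_retained_frac = 0.5) {
  ts <- as_parcel_ts(ts)
  if (length(qc$fd_mm) != nrow(ts$data)) {
    stop("QC trace length does not match the time series")
  }
  mask <- qc$fd_mm <= fd_thresh & qc$dvars_pct <= dvars_thresh
  retained <- mean(mask)
  flagged <- retained < min_retained_frac
  if (flagged) {
    warning(sprintf("insufficient data after scrubbing: %.0f%% retained (%s)",
                    100 * retained, ts$run_id))
  }
  list(ts = ts_with_data_rows(ts, mask), mask = mask,
       retained_frac = retained, flagged = flagged)
}

ts_with_data_rows <- function(ts, mask) {
  out <- ts
  out$data <- ts$data[mask, , drop = FALSE]
  out
}
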