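#' Zero-phase temporal filtering of parcel time series
#'
#' High-pass and low-pass filtering with a 5th-order Butterworth filter
#' applied forward and backward (`signal::filtfilt`), giving zero phase
#' shift and doubled stopband attenuation. Each column is reflect-padded by
#' one cutoff period before filtering to limit edge transients. The
#' high-pass additionally removes column means (DC), mirroring standard
#' fMRI detrending; the low-pass preserves DC exactly.
#'
#' Defaults follow slow event-related preprocessing: a 100-s high-pass
#' applied to all runs, and a 16-s low-pass used as a task-removal method
#' (a conservative cutoff below the 12-s trial frequency, so fluctuations
#' at and above the task frequency are strongly attenuated).
#'
#' @param ts A [parcel_ts()] (or a plain matrix, interpreted at `tr_s`).
#' @param cutoff_s Cutoff period in seconds.
#' @param order Butterworth order (per pass; default 5).
#' @return A [parcel_ts()] of the same shape.
#' @examples
#' ts <- parcel_ts(matrix(rnorm(200), 100, 2), tr_s = 2)
#' lp <- lowpass(ts, 16)
#' @name temporal_filtering
NULL

butter_zero_phase <- function(x, w, type, tr_s, cutoff_s, order) {
  n <- nrow(x)
  if (n * tr_s < cutoff_s) {
    warning(sprintf(
      "run (%g s) is shorter than one cutoff period (%g s); filter is ill-conditioned",
      n * tr_s, cutoff_s))
  }
  flt <- signal::butter(order, w, type = type)
  pad <- min(n - 1L, as.integer(ceiling(cutoff_s / tr_s)))
  apply(x, 2L, function(col) {
    ext <- c(2 * col[1L] - col[(pad + 1L):2L],         # reflected head
             col,
             2 * col[n] - col[(n - 1L):(n - pad)])     # reflected tail
    out <- signal::filtfilt(flt, ext)
    out[(pad + 1L):(pad + n)]
  })
}

#' @rdname temporal_filtering
#' @export
highpass <- function(ts, cutoff_s = 100, order = 5) {
  ts <- as_parcel_ts(ts)
  if (cutoff_s <= 2 * ts$tr_s) {
    stop("`cutoff_s` must exceed twice the sampling interval")
  }
  centered <- sweep(ts$data, 2L, colMeans(ts$data))
  w <- (1 / cutoff_s) / (1 / (2 * ts$tr_s))
  ts_with_data(ts, butter_zero_phase(centered, w, "high", ts$tr_s,
                                     cutoff_s, order))
}

#' @rdname temporal_filtering
#' @export
lowpass <- function(ts, cutoff_s = 16, order = 5) {
  ts <- as_parcel_ts(ts)
  if (cutoff_s < 2 * ts$tr_s) {
    stop("`cutoff_s` must be at least twice the sampling interval (Nyquist)")
  }
  mu <- colMeans(ts$data)
  centered <- sweep(ts$data, 2L, mu)
  w <- (1 / cutoff_s) / (1 / (2 * ts$tr_s))
  out <- butter_zero_phase(centered, w, "low", ts$tr_s, cutoff_s, order)
  ts_with_data(ts, sweep(out, 2L, mu, `+`))
}
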