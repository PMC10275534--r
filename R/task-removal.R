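#' FIR design matrix for a slow event-related run
#'
#' Builds the finite impulse response (FIR) basis: one indicator column per
#' post-stimulus TR bin within the trial window (6 columns for a 12-s
#' window at TR 2 s). Column k (1-based) carries a 1 at volume
#' `round(onset / tr_s) + k` for every trial, 0 elsewhere; this fits an
#' arbitrary evoked-response shape without assuming a canonical HRF.
#' Trials whose window extends past the run contribute only in-run rows.
#'
#' @param onsets Sorted, non-negative trial onset times (seconds).
#' @param tr_s Sampling interval (seconds).
#' @param n_volumes Number of volumes in the run.
#' @param window_trs Number of FIR bins (default 6).
#' @return A list of class `fir_design` with elements `matrix`
#'   (`n_volumes` x `window_trs`), `onset_volumes` (0-based indices) and
#'   `window_trs`.
#' @examples
#' d <- build_fir_design(c(4, 16, 28), tr_s = 2, n_volumes = 20)
#' colSums(d$matrix)
#' @export
build_fir_design <- function(onsets, tr_s, n_volumes, window_trs = 6L) {
  if (is.unsorted(onsets) || any(onsets < 0)) {
    stop("`onsets` must be sorted and non-negative")
  }
  if (tr_s <= 0) stop("`tr_s` must be positive")
  onset_volumes <- as.integer(round(onsets / tr_s))  # 0-based
  if (any(onset_volumes >= n_volumes)) {
    stop("trial onset beyond the end of the run")
  }
  m <- matrix(0, n_volumes, window_trs)
  colnames(m) <- sprintf("fir%02d", seq_len(window_trs))
  for (k in seq_len(window_trs)) {
    rows <- onset_volumes + k       # 1-based row of bin k-1
    rows <- rows[rows <= n_volumes]
    m[rows, k] <- 1
  }
  structure(list(matrix = m, onset_volumes = onset_volumes,
                 window_trs = as.integer(window_trs)),
            class = "fir_design")
}

#' Nuisance regressor matrix
#'
#' Assembles the 18-column nuisance set: six rigid-body motion parameters,
#' cerebrospinal fluid, white matter and global signals, plus the backward
#' temporal derivative of each (row 1 of a derivative is 0 by convention).
#' All columns are mean-centered. Column order is fixed: trans_x, trans_y,
#' trans_z, rot_x, rot_y, rot_z, csf, white_matter, global_signal, then
#' the nine derivatives suffixed `_derivative1`.
#'
#' @param confounds A data.frame (or matrix) with the nine named columns
#'   above (extra columns are ignored with a message).
#' @return Numeric matrix, volumes x 18, mean-centered.
#' @export
build_nuisance <- function(confounds) {
  required <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z",
                "csf", "white_matter", "global_signal")
  confounds <- as.data.frame(confounds)
  missing_cols <- setdiff(required, names(confounds))
  if (length(missing_cols) > 0) {
    stop("confounds are missing required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(confounds), required)
  if (length(extra) > 0) {
    message("ignoring extra confound columns: ", paste(extra, collapse = ", "))
  }
  base <- as.matrix(confounds[required])
  deriv <- rbind(0, diff(base))
  colnames(deriv) <- paste0(required, "_derivative1")
  out <- cbind(base, deriv)
  sweep(out, 2L, colMeans(out))
}

#' Residualize a run against the FIR task model
#'
#' Fits, per parcel, the ordinary least-squares GLM
#' `signal ~ intercept + FIR basis + nuisance regressors` and returns the
#' residual time series — activity not accounted for by the task, the "FIR"
#' background-connectivity dataset. Exactly collinear columns (after
#' centering) are dropped with a warning naming them; a model that is still
#' rank deficient is an error.
#'
#' @param ts A [parcel_ts()].
#' @param design A [build_fir_design()] result.
#' @param nuisance Optional matrix from [build_nuisance()] (row count must
#'   match); `NULL` fits the FIR model alone.
#' @return A [parcel_ts()] of residuals (same shape as the input).
#' @export
fir_residuals <- function(ts, design, nuisance = NULL) {
  ts <- as_parcel_ts(ts)
  n <- nrow(ts$data)
  if (nrow(design$matrix) != n) {
    stop("design matrix row count does not match the time series")
  }
  x <- cbind(intercept = 1, design$matrix)
  if (!is.null(nuisance)) {
    if (nrow(nuisance) != n) {
      stop("nuisance matrix row count does not match the time series")
    }
    x <- cbind(x, nuisance)
  }
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    dropped <- colnames(x)[qx$pivot[(qx$rank + 1L):ncol(x)]]
    warning("dropping exactly collinear model columns: ",
            paste(dropped, collapse = ", "))
    x <- x[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    qx <- qr(x)
    if (qx$rank < ncol(x)) {
      stop("model rank deficient after pruning; offending columns: ",
           paste(colnames(x)[qx$pivot[(qx$rank + 1L):ncol(x)]],
                 collapse = ", "))
    }
  }
  ts_with_data(ts, qr.resid(qx, ts$data))
}

#' Low-pass task-removal dataset
#'
#' The "LPF" background-connectivity dataset: the task run low-pass filtered
#' with a 16-s cutoff, removing fluctuations at and above the 12-s task
#' frequency while preserving slower background activity. Thin wrapper over
#' [lowpass()] kept as the named counterpart of [fir_residuals()].
#'
#' @param ts A [parcel_ts()] task run.
#' @param cutoff_s Low-pass cutoff (seconds, default 16).
#' @return A [parcel_ts()].
#' @export
lpf_dataset <- function(ts, cutoff_s = 16) {
  lowpass(ts, cutoff_s = cutoff_s)
}
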