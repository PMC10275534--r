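#' Connectivity matrix container
#'
#' Symmetric parcels x parcels matrix of Fisher-z connectivity values with
#' the method that produced it. The diagonal is stored as 0 and excluded
#' from every downstream statistic.
#'
#' @param z Symmetric numeric matrix (Fisher-z scale).
#' @param method One of `"rest"`, `"lpf"`, `"fir"`, `"raw"`.
#' @param subject_id Subject identifier.
#' @param n_volumes_used Volumes that contributed (post-scrubbing).
#' @param parcel_ids Parcel identifiers (defaults to `z`'s dimnames).
#' @return An object of class `conn_matrix`.
#' @export
conn_matrix <- function(z, method = c("rest", "lpf", "fir", "raw"),
                        subject_id = NA_character_, n_volumes_used = NA_integer_,
                        parcel_ids = NULL) {
  method <- match.arg(method)
  z <- as.matrix(z)
  if (nrow(z) != ncol(z)) stop("`z` must be square")
  if (max(abs(z - t(z))) > 1e-8) stop("`z` must be symmetric")
  if (any(!is.finite(z))) stop("`z` must be finite")
  if (is.null(parcel_ids)) {
    parcel_ids <- rownames(z)
    if (is.null(parcel_ids)) parcel_ids <- sprintf("p%03d", seq_len(nrow(z)))
  }
  diag(z) <- 0
  dimnames(z) <- list(parcel_ids, parcel_ids)
  structure(
    list(z = z, method = method, subject_id = subject_id,
         n_volumes_used = n_volumes_used, parcel_ids = parcel_ids),
    class = "conn_matrix"
  )
}

#' @export
print.conn_matrix <- function(x, ...) {
  cat(sprintf("<conn_matrix> %s %s: %d parcels, %s volumes used\n",
              x$subject_id, x$method, length(x$parcel_ids),
              format(x$n_volumes_used)))
  invisible(x)
}

#' Nuisance-controlled partial correlation matrix
#'
#' Residualizes every parcel series on an intercept plus the nuisance
#' regressors, then computes all pairwise Pearson correlations of the
#' residuals. This equals the partial correlation controlling for the
#' nuisance set (each pair of parcels controlled for the same covariates,
#' not for the other parcels). With `nuisance = NULL` it reduces to the
#' plain correlation matrix.
#'
#' @param ts A (scrubbed) [parcel_ts()].
#' @param nuisance Optional volumes x q nuisance matrix, rows aligned with
#'   `ts` (scrub it with the same mask).
#' @return Correlation matrix (r scale, unit diagonal).
#' @export
partial_corr_matrix <- function(ts, nuisance = NULL) {
  ts <- as_parcel_ts(ts)
  n <- nrow(ts$data)
  q <- if (is.null(nuisance)) 0L else ncol(nuisance)
  if (n <= q + 2L) {
    stop(sprintf(
      "insufficient degrees of freedom: %d volumes for %d nuisance columns",
      n, q))
  }
  x <- cbind(intercept = rep(1, n), nuisance)
  if (!is.null(nuisance) && nrow(nuisance) != n) {
    stop("nuisance rows do not align with the time series")
  }
  resid <- qr.resid(qr(x), ts$data)
  r <- stats::cor(resid)
  dimnames(r) <- list(ts$parcel_ids, ts$parcel_ids)
  r
}

#' Fisher z transform and its inverse
#'
#' `fisher_z()` maps correlations to the variance-stabilized scale
#' `z = atanh(r)`; correlations are clipped to `1 - 1e-7` in absolute value
#' first so that r = 1 (identical series) maps to a finite, large z.
#' `inverse_fisher_z()` maps back with `tanh`.
#'
#' @param r Correlation(s) in `[-1, 1]` (vector or matrix).
#' @param z Fisher-z value(s).
#' @return Numeric of the same shape.
#' @examples
#' fisher_z(0.5)            # 0.5493061
#' inverse_fisher_z(fisher_z(0.3))
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) {
    stop("correlations must lie in [-1, 1]")
  }
  atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))
}

#' @rdname fisher_z
#' @export
inverse_fisher_z <- function(z) tanh(z)

#' Build a Fisher-z connectivity matrix from one run
#'
#' [partial_corr_matrix()] followed by [fisher_z()], with the diagonal set
#' to 0, packaged as a [conn_matrix()].
#'
#' @inheritParams partial_corr_matrix
#' @inheritParams conn_matrix
#' @return A [conn_matrix()].
#' @export
connectivity_matrix <- function(ts, nuisance = NULL,
                                method = c("rest", "lpf", "fir", "raw"),
                                subject_id = NA_character_) {
  r <- partial_corr_matrix(ts, nuisance)
  z <- fisher_z(r)
  diag(z) <- 0
  conn_matrix(z, method = match.arg(method), subject_id = subject_id,
              n_volumes_used = nrow(ts$data), parcel_ids = ts$parcel_ids)
}

#' Average connectivity matrices across runs
#'
#' Entrywise mean of the Fisher-z matrices (the scale on which connectivity
#' is averaged and tested); supports subjects with fewer than the full
#' complement of runs.
#'
#' @param mats List of [conn_matrix()] objects with identical method,
#'   subject and parcel order.
#' @return A [conn_matrix()] with `n_volumes_used` summed.
#' @export
average_runs <- function(mats) {
  if (length(mats) < 1L) stop("need at least one matrix")
  ref <- mats[[1L]]
  for (m in mats[-1L]) {
    if (!identical(m$parcel_ids, ref$parcel_ids)) {
      stop("parcel order differs between runs")
    }
    if (!identical(m$method, ref$method)) {
      stop("cannot average matrices from different methods")
    }
  }
  z <- Reduce(`+`, lapply(mats, `[[`, "z")) / length(mats)
  conn_matrix(z, method = ref$method, subject_id = ref$subject_id,
              n_volumes_used = sum(vapply(mats, `[[`, 0L, "n_volumes_used")),
              parcel_ids = ref$parcel_ids)
}

#' Vectorize the strict upper triangle
#'
#' Row-major order: (1,2), (1,3), ..., (1,p), (2,3), ... — length
#' p(p-1)/2 (4950 unique connections for 100 parcels). The inverse,
#' [unvectorize_upper()], rebuilds the symmetric matrix with zero diagonal.
#'
#' @param mat A [conn_matrix()] or symmetric matrix.
#' @return Numeric vector of length `p * (p - 1) / 2`.
#' @export
vectorize_upper <- function(mat) {
  z <- if (inherits(mat, "conn_matrix")) mat$z else as.matrix(mat)
  t(z)[lower.tri(z)]     # row-major strict upper triangle
}

#' @rdname vectorize_upper
#' @param v Vector of length `p * (p - 1) / 2`.
#' @param parcel_ids Optional dimnames for the rebuilt matrix.
#' @export
unvectorize_upper <- function(v, parcel_ids = NULL) {
  p <- (1 + sqrt(1 + 8 * length(v))) / 2
  if (abs(p - round(p)) > 1e-9) {
    stop("length is not p(p-1)/2 for an integer p")
  }
  p <- as.integer(round(p))
  m <- matrix(0, p, p)
  m[lower.tri(m)] <- v    # fill column-major lower = row-major upper
  m <- m + t(m)
  if (!is.null(parcel_ids)) dimnames(m) <- list(parcel_ids, parcel_ids)
  m
}

#' Pair labels matching [vectorize_upper()] order
#'
#' @param parcel_ids Character vector of parcel identifiers.
#' @return data.frame with columns `parcel_a`, `parcel_b`, one row per
#'   unique pair, in vectorization order.
#' @export
upper_pairs <- function(parcel_ids) {
  p <- length(parcel_ids)
  idx <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  data.frame(parcel_a = parcel_ids[idx[, 1L]],
             parcel_b = parcel_ids[idx[, 2L]],
             stringsAsFactors = FALSE)
}
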