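#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties averaged), via
#' `stats::cor(..., method = "spearman")`, with explicit error contracts:
#' inputs must have equal length, at least 3 observations, and must not be
#' constant (rho is undefined for a constant vector).
#'
#' @param x,y Numeric vectors.
#' @return Spearman's rho.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("inputs contain missing values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Spearman rho undefined for constant input")
  }
  stats::cor(x, y, method = "spearman")
}

# Fisher-z mean of correlations, reported back-transformed ("mean rho(z)").
mean_rho_z <- function(rho) {
  rho <- rho[!is.na(rho)]
  inverse_fisher_z(mean(fisher_z(rho)))
}

#' Fingerprint similarity between two connectivity matrices
#'
#' Spearman rank correlation between the vectorized strict upper triangles
#' of two subject-level connectivity matrices — how closely one method's
#' whole-brain connectivity pattern matches another's for the same subject.
#'
#' @param a,b [conn_matrix()] objects with identical parcel order.
#' @return Spearman's rho.
#' @export
fingerprint_similarity <- function(a, b) {
  if (!identical(a$parcel_ids, b$parcel_ids)) {
    stop("parcel order differs between matrices")
  }
  spearman(vectorize_upper(a), vectorize_upper(b))
}

# Resolve an atlas (data.frame parcel_id/network, or a vector) to a network
# factor aligned with `parcel_ids`; level order = order of first appearance.
network_factor <- function(labels, parcel_ids) {
  if (is.data.frame(labels)) {
    if (!all(c("parcel_id", "network") %in% names(labels))) {
      stop("atlas labels need columns `parcel_id` and `network`")
    }
    idx <- match(parcel_ids, labels$parcel_id)
    if (anyNA(idx)) {
      stop("atlas does not label parcels: ",
           paste(parcel_ids[is.na(idx)], collapse = ", "))
    }
    v <- labels$network[idx]
  } else {
    v <- as.character(labels)
    if (!is.null(names(v)) && all(parcel_ids %in% names(v))) {
      v <- v[parcel_ids]
    }
    if (length(v) != length(parcel_ids)) {
      stop("labels must cover every parcel")
    }
  }
  factor(v, levels = unique(v))
}

#' Mean within- and between-network connectivity
#'
#' Averages the unique (upper-triangle) connection values joining parcels
#' of the same network (`within`) and of different networks (`between`).
#' A network with a single parcel contributes no within-network pairs.
#'
#' @param mat A [conn_matrix()] (Fisher-z scale).
#' @param labels Atlas labels: a data.frame with `parcel_id`, `network`, or
#'   a character vector aligned with the parcels.
#' @return Named numeric vector `c(within = , between = )`.
#' @export
within_between <- function(mat, labels) {
  net <- network_factor(labels, mat$parcel_ids)
  v <- vectorize_upper(mat)
  pairs <- upper_pair_indices(length(net))
  same <- net[pairs[, 1L]] == net[pairs[, 2L]]
  c(within = mean(v[same]), between = mean(v[!same]))
}

# strict upper-triangle (i, j) indices in row-major vectorization order
upper_pair_indices <- function(p) {
  idx <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}

#' Collapse a connectivity matrix to the network level
#'
#' Entry (m, n) of the returned matrix is the mean of the unique
#' parcel-pair values connecting networks m and n (for m = n, the unique
#' within-network pairs; the diagonal of the parcel matrix is excluded).
#' With 7 networks this yields 28 unique values (7 within + 21 between).
#'
#' @inheritParams within_between
#' @return Symmetric k x k matrix, k = number of networks.
#' @export
collapse_networks <- function(mat, labels) {
  net <- network_factor(labels, mat$parcel_ids)
  k <- nlevels(net)
  v <- vectorize_upper(mat)
  pairs <- upper_pair_indices(length(net))
  a <- as.integer(net[pairs[, 1L]])
  b <- as.integer(net[pairs[, 2L]])
  lo <- pmin(a, b); hi <- pmax(a, b)
  out <- matrix(NA_real_, k, k, dimnames = list(levels(net), levels(net)))
  sums <- tapply(v, list(lo, hi), mean)
  for (i in seq_len(k)) for (j in i:k) {
    m <- sums[as.character(i), as.character(j)]
    out[i, j] <- out[j, i] <- m
  }
  out
}

#' Across-subject stability of individual differences, per connection
#'
#' For each unique parcel-pair connection, the Spearman correlation across
#' subjects between the connectivity estimates of two methods: does a
#' subject with a strong connection under method A also show it under
#' method B? Connections constant across subjects in either cohort yield
#' `NA` (undefined rho) and are excluded from summaries, with their count
#' attached as `attr(, "n_undefined")`.
#'
#' @param cohort_a,cohort_b Lists of [conn_matrix()], same subjects in the
#'   same order, same parcel order.
#' @return Numeric vector of rho, length p(p-1)/2, in
#'   [vectorize_upper()] order.
#' @export
connectionwise_stability <- function(cohort_a, cohort_b) {
  stopifnot(length(cohort_a) == length(cohort_b))
  if (length(cohort_a) < 4L) stop("need at least 4 subjects")
  va <- vapply(cohort_a, vectorize_upper,
               numeric(length(vectorize_upper(cohort_a[[1L]]))))
  vb <- vapply(cohort_b, vectorize_upper, numeric(nrow(va)))
  ra <- apply(va, 1L, rank)   # subjects x connections
  rb <- apply(vb, 1L, rank)
  sa <- apply(va, 1L, stats::sd)
  sb <- apply(vb, 1L, stats::sd)
  rho <- suppressWarnings(
    vapply(seq_len(nrow(va)), function(i) {
      stats::cor(ra[, i], rb[, i])
    }, 0)
  )
  rho[sa == 0 | sb == 0] <- NA_real_
  n_undef <- sum(is.na(rho))
  if (n_undef > 0) {
    message(n_undef, " connection(s) constant across subjects; rho undefined")
  }
  attr(rho, "n_undefined") <- n_undef
  rho
}

#' Across-subject stability at the network level
#'
#' Collapses each subject's matrix to networks ([collapse_networks()]) and
#' computes, for each unique network pair (including within-network cells),
#' the across-subject Spearman correlation between the two methods.
#'
#' @inheritParams connectionwise_stability
#' @param labels Atlas labels (see [within_between()]).
#' @return Symmetric k x k matrix of rho (28 unique values for 7 networks).
#' @export
network_stability <- function(cohort_a, cohort_b, labels) {
  stopifnot(length(cohort_a) == length(cohort_b))
  if (length(cohort_a) < 4L) stop("need at least 4 subjects")
  ca <- lapply(cohort_a, collapse_networks, labels = labels)
  cb <- lapply(cohort_b, collapse_networks, labels = labels)
  k <- nrow(ca[[1L]])
  out <- matrix(NA_real_, k, k, dimnames = dimnames(ca[[1L]]))
  for (i in seq_len(k)) for (j in i:k) {
    xa <- vapply(ca, function(m) m[i, j], 0)
    xb <- vapply(cb, function(m) m[i, j], 0)
    out[i, j] <- out[j, i] <-
      if (stats::sd(xa) == 0 || stats::sd(xb) == 0) NA_real_
      else stats::cor(xa, xb, method = "spearman")
  }
  out
}

#' Summary statistics for a set of stability correlations
#'
#' @param rho Numeric vector of Spearman rho values (NA excluded).
#' @return data.frame with `mean`, `median`, `sd`, `min`, `max`, `n`.
#' @export
stability_summary <- function(rho) {
  rho <- rho[!is.na(rho)]
  data.frame(mean = mean(rho), median = stats::median(rho),
             sd = stats::sd(rho), min = min(rho), max = max(rho),
             n = length(rho))
}

#' Subject identification from connectivity fingerprints
#'
#' For each subject's matrix in cohort A, finds the cohort-B matrix with
#' the highest [fingerprint_similarity()]; accuracy is the fraction of
#' subjects matched to themselves. Ties are broken toward the lowest
#' subject index (with a message).
#'
#' @inheritParams connectionwise_stability
#' @return A list: `accuracy` (fraction), `matched` (index of the best
#'   B-match per A-subject), `similarity` (full A x B rho matrix).
#' @export
identify_subjects <- function(cohort_a, cohort_b) {
  stopifnot(length(cohort_a) == length(cohort_b))
  n <- length(cohort_a)
  sim <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    sim[i, j] <- fingerprint_similarity(cohort_a[[i]], cohort_b[[j]])
  }
  matched <- apply(sim, 1L, function(row) {
    best <- which(row == max(row))
    if (length(best) > 1L) message("identification tie broken to lowest index")
    best[1L]
  })
  list(accuracy = mean(matched == seq_len(n)), matched = matched,
       similarity = sim)
}

#' Association between similarity scores and head motion
#'
#' Correlates per-subject rest-task pattern-similarity scores with QC
#' summaries (one column per motion index, e.g. mean/max FD and DVARS),
#' reporting Spearman's rho and a two-sided p-value per index.
#'
#' @param similarity_scores Numeric vector, one score per subject.
#' @param qc_summaries data.frame of per-subject QC indices (>= 4 rows).
#' @return data.frame with columns `index`, `rho`, `p`.
#' @export
motion_association <- function(similarity_scores, qc_summaries) {
  qc_summaries <- as.data.frame(qc_summaries)
  if (nrow(qc_summaries) != length(similarity_scores)) {
    stop("QC summaries and similarity scores must cover the same subjects")
  }
  if (length(similarity_scores) < 4L) stop("need at least 4 subjects")
  res <- lapply(names(qc_summaries), function(nm) {
    ct <- suppressWarnings(
      stats::cor.test(similarity_scores, qc_summaries[[nm]],
                      method = "spearman", exact = FALSE))
    data.frame(index = nm, rho = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
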