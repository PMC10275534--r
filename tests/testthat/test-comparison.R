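test_that("spearman handles monotone transforms, reversals and ties", {
  x <- c(0.2, 1.4, 2.2, 3.9, 5.0)
  expect_equal(spearman(x, exp(x)), 1)
  expect_equal(spearman(x, rev(x)), -1)
  xt <- c(1, 2, 2, 4); yt <- c(3, 1, 4, 4)
  expect_equal(spearman(xt, yt), oracle_spearman(xt, yt), tolerance = 1e-12)
  set.seed(10)
  for (i in 1:5) {
    a <- sample(1:6, 10, replace = TRUE)
    b <- sample(1:6, 10, replace = TRUE)
    expect_equal(spearman(a, b), oracle_spearman(a, b), tolerance = 1e-12)
  }
  expect_error(spearman(rep(1, 5), 1:5), "constant")
  expect_error(spearman(1:2, 1:2), "at least 3")
})

random_conn <- function(p = 6, method = "rest", subject_id = "sub-01") {
  m <- matrix(rnorm(p * p, sd = 0.4), p, p)
  m <- (m + t(m)) / 2; diag(m) <- 0
  conn_matrix(m, method = method, subject_id = subject_id)
}

test_that("fingerprint similarity is 1 for self and rank-invariant", {
  set.seed(11)
  a <- random_conn()
  expect_equal(fingerprint_similarity(a, a), 1)
  b <- a
  b$z <- tanh(a$z) * 3 + 2   # strictly monotone entrywise transform
  diag(b$z) <- 0
  expect_equal(fingerprint_similarity(a, b), 1)
  c2 <- random_conn()
  c2$parcel_ids <- rev(c2$parcel_ids)
  expect_error(fingerprint_similarity(a, c2), "parcel order")
})

toy_block_conn <- function() {
  z <- matrix(0.1, 4, 4)
  z[1:2, 1:2] <- 0.5
  z[3:4, 3:4] <- 0.5
  diag(z) <- 0
  conn_matrix(z, method = "rest")
}

toy_labels <- data.frame(parcel_id = sprintf("p%03d", 1:4),
                         network = c("N1", "N1", "N2", "N2"))

test_that("within/between means and network collapsing are exact on a block toy", {
  mat <- toy_block_conn()
  wb <- within_between(mat, toy_labels)
  expect_equal(unname(wb), c(0.5, 0.1))

  swapped <- toy_labels
  swapped$network <- c("N2", "N2", "N1", "N1")
  expect_equal(unname(within_between(mat, swapped)), c(0.5, 0.1))

  cm <- collapse_networks(mat, toy_labels)
  expect_equal(unname(cm), matrix(c(0.5, 0.1, 0.1, 0.5), 2, 2))
})

test_that("network collapse is a pair-count weighted partition of the grand mean", {
  set.seed(12)
  mat <- random_conn(p = 10)
  labels <- data.frame(parcel_id = mat$parcel_ids,
                       network = rep(c("A", "B", "C"), c(3, 3, 4)))
  cm <- collapse_networks(mat, labels)
  sizes <- c(3, 3, 4)
  pair_counts <- outer(sizes, sizes)
  diag(pair_counts) <- sizes * (sizes - 1) / 2
  pair_counts[lower.tri(pair_counts)] <- 0
  w <- pair_counts[upper.tri(pair_counts, diag = TRUE)]
  vals <- cm[upper.tri(cm, diag = TRUE)]
  expect_equal(sum(vals * w) / sum(w), mean(vectorize_upper(mat)))

  labels7 <- data.frame(parcel_id = sprintf("p%03d", 1:100),
                        network = rep(paste0("N", 1:7),
                                      c(15, 15, 14, 14, 14, 14, 14)))
  big <- random_conn(p = 100)
  cm7 <- collapse_networks(big, labels7)
  expect_equal(sum(upper.tri(cm7, diag = TRUE)), 28L)
})

test_that("connection-wise stability: identity, permutation null, undefined rho", {
  set.seed(13)
  cohort <- lapply(1:20, function(i) random_conn(p = 6))
  self <- connectionwise_stability(cohort, cohort)
  expect_equal(self, rep(1, 15), ignore_attr = TRUE)

  permuted <- cohort[c(2:20, 1)]
  null_rho <- connectionwise_stability(cohort, permuted)
  expect_lt(abs(mean(null_rho)), 0.1)

  flat <- lapply(cohort, function(m) { m$z[1, 2] <- m$z[2, 1] <- 0.3; m })
  expect_message(rho <- connectionwise_stability(flat, cohort), "undefined")
  expect_true(is.na(rho[1]))
  expect_equal(attr(rho, "n_undefined"), 1L)
  expect_error(connectionwise_stability(cohort[1:3], cohort[1:3]), "4 subjects")
})

test_that("subject identification: self-match, chance level, tie handling", {
  set.seed(14)
  cohort <- lapply(1:12, function(i) random_conn(p = 8))
  self <- identify_subjects(cohort, cohort)
  expect_equal(self$accuracy, 1.0)
  expect_equal(self$matched, 1:12)

  accs <- sapply(1:8, function(s) {
    noise <- lapply(1:12, function(i) random_conn(p = 8))
    identify_subjects(cohort, noise)$accuracy
  })
  expect_lt(mean(accs), 3 / 12)   # about chance (1/12) over seeds
})

test_that("motion association returns one rho and p per QC index", {
  set.seed(15)
  qc <- data.frame(mean_fd = runif(20), max_fd = runif(20),
                   mean_dvars = runif(20), max_dvars = runif(20))
  res <- motion_association(qc$mean_fd, qc)
  expect_equal(nrow(res), 4L)
  expect_equal(res$rho[res$index == "mean_fd"], 1)
  expect_true(all(res$p >= 0 & res$p <= 1))

  # independence: strong associations are rare across replicates
  hits <- sapply(1:20, function(i) {
    scores <- rnorm(56)
    qc2 <- data.frame(mean_fd = runif(56))
    abs(motion_association(scores, qc2)$rho) > 0.5
  })
  expect_lt(mean(hits), 0.1)
  expect_error(motion_association(rnorm(3), qc[1:3, ]), "4 subjects")
})

test_that("stability outputs are invariant to monotone transforms of input", {
  set.seed(16)
  cohort_a <- lapply(1:8, function(i) random_conn(p = 5))
  cohort_b <- lapply(1:8, function(i) random_conn(p = 5))
  warped <- lapply(cohort_b, function(m) {
    m$z <- exp(m$z); diag(m$z) <- 0; m
  })
  expect_equal(connectionwise_stability(cohort_a, cohort_b),
               connectionwise_stability(cohort_a, warped))
  sims1 <- sapply(1:8, function(i) {
    fingerprint_similarity(cohort_a[[i]], cohort_b[[i]])
  })
  sims2 <- sapply(1:8, function(i) {
    fingerprint_similarity(cohort_a[[i]], warped[[i]])
  })
  expect_equal(sims1, sims2)
})
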