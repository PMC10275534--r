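test_that("FIR design places indicator columns from rounded onsets", {
  onsets <- seq(4, 208, by = 12)
  d <- build_fir_design(onsets, tr_s = 2, n_volumes = 110)
  expect_equal(dim(d$matrix), c(110L, 6L))
  # bin 0 rows: 0-based volumes 2, 8, ..., 104 -> 1-based 3, 9, ..., 105
  expect_equal(which(d$matrix[, 1] == 1), seq(3, 105, by = 6))
  expect_equal(unname(colSums(d$matrix)), rep(18, 6))

  single <- build_fir_design(0, tr_s = 2, n_volumes = 6)
  expect_equal(unname(single$matrix), diag(6))

  # 12-s spacing at a 12-s window: columns pairwise orthogonal
  expect_equal(max(abs(crossprod(d$matrix) - diag(colSums(d$matrix)))), 0)

  expect_error(build_fir_design(300, tr_s = 2, n_volumes = 110), "beyond")
  expect_error(build_fir_design(c(16, 4), tr_s = 2, n_volumes = 110), "sorted")
})

test_that("nuisance matrix has 18 centered columns with backward-difference derivatives", {
  n <- 10
  conf <- data.frame(
    trans_x = seq(0, 0.9, by = 0.1), trans_y = 0, trans_z = 0,
    rot_x = 0, rot_y = 0, rot_z = 0,
    csf = rnorm(n), white_matter = rnorm(n), global_signal = rnorm(n))
  nm <- build_nuisance(conf)
  expect_equal(ncol(nm), 18L)
  expect_equal(unname(colMeans(nm)), rep(0, 18), tolerance = 1e-12)
  # ramp slope 0.1/volume -> derivative constant 0.1 from row 2 (pre-centering)
  deriv <- nm[, "trans_x_derivative1"] - mean(nm[, "trans_x_derivative1"]) +
    mean(c(0, rep(0.1, n - 1)))
  expect_equal(deriv[-1], rep(0.1, n - 1), tolerance = 1e-12)

  const <- data.frame(trans_x = 1, trans_y = 1, trans_z = 1, rot_x = 1,
                      rot_y = 1, rot_z = 1, csf = 1, white_matter = 1,
                      global_signal = 1)[rep(1, 5), ]
  nm_const <- build_nuisance(const)
  # centered constants vanish; derivative columns are 0 except the row-1 kink
  expect_lt(max(abs(nm_const[, 1:9])), 1e-12)
  expect_error(build_nuisance(conf[, -7]), "missing")
})

test_that("FIR residuals annihilate model-space signal and match a normal-equations oracle", {
  set.seed(11)
  d <- build_fir_design(c(0, 12, 24), tr_s = 2, n_volumes = 20)
  betas <- rnorm(6)
  in_span <- parcel_ts(cbind(d$matrix %*% betas, 2 * d$matrix %*% rev(betas)),
                       tr_s = 2)
  res <- fir_residuals(in_span, d)
  expect_lt(max(abs(res$data)), 1e-8)

  y <- matrix(rnorm(20 * 3), 20, 3)
  nuis <- matrix(rnorm(20 * 2), 20, 2)
  colnames(nuis) <- c("n1", "n2")
  got <- fir_residuals(parcel_ts(y, tr_s = 2), d, nuis)$data
  x <- cbind(1, d$matrix, nuis)
  oracle <- y - x %*% solve(t(x) %*% x, t(x) %*% y)
  expect_equal(unname(got), unname(oracle), tolerance = 1e-10)

  # residuals orthogonal to every regressor
  expect_lt(max(abs(crossprod(x, got))) / nrow(y), 1e-8)
  # projection never increases variance
  expect_true(all(apply(got, 2, var) <= apply(y, 2, var)))
})

test_that("noise-free residuals recover the intrinsic component", {
  spec <- tiny_spec(noise_sd = 0, confound_loading_sd = 0, spike_prob = 0,
                    task_amplitude = 2)
  sub <- simulate_subject(spec, 1)
  run <- sub$task_runs[[1]]
  d <- build_fir_design(run$onsets, spec$tr_s, nrow(run$ts$data))
  res <- fir_residuals(run$ts, d)
  # reconstruct the intrinsic-only series: same stream minus the evoked term
  no_task <- simulate_subject(tiny_spec(noise_sd = 0, confound_loading_sd = 0,
                                        spike_prob = 0, task_amplitude = 0), 1)
  intrinsic <- no_task$task_runs[[1]]$ts$data

  # projection identity: with the evoked term inside the model span, the
  # residuals equal the intrinsic signal minus its projection on the model
  x <- cbind(1, d$matrix)
  oracle <- intrinsic - x %*% solve(t(x) %*% x, t(x) %*% intrinsic)
  expect_equal(unname(res$data), unname(oracle), tolerance = 1e-8)

  cors <- sapply(seq_len(ncol(intrinsic)), function(j) {
    cor(res$data[, j], intrinsic[, j] - mean(intrinsic[, j]))
  })
  expect_gt(median(cors), 0.95)
  expect_true(all(cors > 0.9))
})

test_that("collinear model columns are pruned with a warning, not silently", {
  d <- build_fir_design(c(0, 12), tr_s = 2, n_volumes = 12)
  nuis <- cbind(dup = d$matrix[, 1], ok = rnorm(12))
  expect_warning(
    res <- fir_residuals(parcel_ts(matrix(rnorm(24), 12, 2), tr_s = 2),
                         d, nuis),
    "collinear")
  expect_equal(dim(res$data), c(12L, 2L))
})

test_that("both removal methods flatten the trial-locked mean response", {
  spec <- ground_truth_spec(n_subjects = 1, seed = 9)
  sub <- simulate_subject(spec, 1)
  run <- sub$task_runs[[1]]
  responsive <- which(spec$task_amplitude > 1)
  onset_vols <- as.integer(round(run$onsets / spec$tr_s))

  trial_locked_peak <- function(mat) {
    epochs <- sapply(onset_vols, function(ov) {
      rowMeans(mat[(ov + 1):(ov + 6), responsive, drop = FALSE])
    })
    m <- rowMeans(epochs)
    max(abs(m - mean(m)))
  }

  hp <- highpass(run$ts, 100)
  raw_peak <- trial_locked_peak(hp$data)
  lpf_peak <- trial_locked_peak(lowpass(hp, 16)$data)
  d <- build_fir_design(run$onsets, spec$tr_s, nrow(run$ts$data))
  fir_peak <- trial_locked_peak(
    fir_residuals(hp, d, build_nuisance(run$confounds))$data)

  expect_lt(lpf_peak, 0.1 * raw_peak)
  expect_lt(fir_peak, 0.1 * raw_peak)
})

test_that("FIR residuals keep intrinsic spectral content outside task bins", {
  spec <- tiny_spec(noise_sd = 0, confound_loading_sd = 0, spike_prob = 0,
                    task_amplitude = 2, seed = 13)
  sub <- simulate_subject(spec, 1)
  run <- sub$task_runs[[1]]
  intrinsic <- simulate_subject(
    tiny_spec(noise_sd = 0, confound_loading_sd = 0, spike_prob = 0,
              task_amplitude = 0, seed = 13), 1)$task_runs[[1]]$ts$data
  d <- build_fir_design(run$onsets, spec$tr_s, nrow(run$ts$data))
  res <- fir_residuals(run$ts, d)

  pg <- function(x) stats::spec.pgram(stats::ts(x, deltat = spec$tr_s),
                                      taper = 0, detrend = TRUE,
                                      plot = FALSE)
  f_task <- 1 / spec$trial_spacing_s
  band_mean <- function(x) {
    s <- pg(x)
    keep <- abs(s$freq %% f_task) > 0.01 & abs(s$freq %% f_task - f_task) > 0.01
    mean(s$spec[keep])
  }
  ratios <- sapply(seq_len(ncol(intrinsic)), function(j) {
    band_mean(res$data[, j]) / band_mean(intrinsic[, j])
  })
  expect_true(all(abs(ratios - 1) < 0.10))
})

test_that("lpf_dataset removes nearly all variance at the task frequency", {
  spec <- ground_truth_spec(n_subjects = 1, seed = 21)
  run <- simulate_subject(spec, 1)$task_runs[[1]]
  responsive <- which(spec$task_amplitude > 1)[1]
  x <- run$ts$data[, responsive]
  lp <- lpf_dataset(run$ts)$data[, responsive]
  # light taper keeps sidelobe leakage from passband power out of the bin
  pg <- function(v) stats::spec.pgram(stats::ts(v, deltat = spec$tr_s),
                                      taper = 0.1, detrend = TRUE,
                                      plot = FALSE)
  f_task <- 1 / spec$trial_spacing_s
  at_task <- function(s) s$spec[which.min(abs(s$freq - f_task))]
  expect_lt(at_task(pg(lp)) / at_task(pg(x)), 0.01)

  zero <- parcel_ts(matrix(0, 110, 2) + 0, tr_s = 2)
  expect_lt(max(abs(lpf_dataset(zero)$data)), 1e-12)
})
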