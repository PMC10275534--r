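#' Ground-truth specification for a synthetic cohort
#'
#' Defines the generative model for a multi-subject, multi-run synthetic
#' dataset of parcel-level BOLD time series with known intrinsic (background)
#' connectivity. The design emulates a slow event-related study: one 8-min
#' rest run and four 3.67-min passive-viewing runs per subject at TR 2 s,
#' with trials every 12 s (2 s stimulus + 10 s fixation) after a 4-s initial
#' fixation, 18 trials per run.
#'
#' The intrinsic signal of subject *i* is a stationary AR(1) process whose
#' cross-parcel covariance is a block-structured correlation matrix
#' (`r_within` inside the 7 network blocks, `r_between` elsewhere) perturbed
#' by subject-idiosyncratic jitter — the "connectivity fingerprint". Task
#' runs add a trial-locked evoked response (`evoked_shape` scaled by
#' `task_amplitude` per parcel), and every run adds confound contamination
#' (physiological signals times per-parcel loadings), white measurement
#' noise, and occasional head-motion spikes.
#'
#' @param n_subjects Number of subjects (default 56).
#' @param n_parcels Number of parcels (default 100).
#' @param network_sizes Integer vector of parcels per network, summing to
#'   `n_parcels`; 7 networks by default.
#' @param network_names Labels for the networks.
#' @param r_within,r_between True correlation inside / between network
#'   blocks. Must satisfy `r_within > r_between` in the default regime.
#' @param subject_jitter_sd SD of the per-subject perturbation added to each
#'   true off-diagonal correlation (default 0.05).
#' @param ar_coefficient AR(1) parameter of the intrinsic process in `[0, 1)`
#'   (default 0.4): makes the intrinsic signal red but broadband, so a
#'   low-pass filter discards genuine fast intrinsic fluctuations.
#' @param tr_s Sampling interval, seconds (default 2).
#' @param rest_duration_s Rest run length, seconds (default 480).
#' @param n_task_runs Number of task runs (default 4).
#' @param task_duration_s Task run length, seconds (default 220 = 3.67 min).
#' @param initial_fixation_s Fixation before the first trial (default 4 s).
#' @param trial_spacing_s Trial onset asynchrony (default 12 s).
#' @param n_trials_per_run Trials per task run (default 18).
#' @param task_amplitude Per-parcel evoked peak amplitude (signal units).
#'   `NULL` (default) gives 2.0 for parcels in the Visual and Dorsal
#'   Attention networks and 0.3 elsewhere.
#' @param evoked_shape Per-TR evoked response template within the 12-s trial
#'   window; 6 samples at TR 2 s, default `c(0, .6, 1, .7, .3, .1)`.
#' @param baseline Mean signal level added to every parcel (arbitrary units,
#'   default 1000); gives the DVARS percentage a realistic denominator.
#' @param confound_sd Marginal SD of the physiological confound signals.
#' @param confound_loading_sd SD of the per-parcel confound weights.
#' @param noise_sd White measurement noise SD.
#' @param spike_prob Per-volume probability of a motion spike.
#' @param spike_magnitude_mm Translation step (mm) of an injected spike.
#' @param spike_signal_jump SD of the transient per-parcel signal glitch
#'   (signal units) at a spike volume. The default (3) corrupts the spike
#'   volume visibly but stays below the default DVARS threshold, so at
#'   default settings spikes are censored via FD at exactly the injected
#'   volumes.
#' @param seed Master RNG seed. Subject *i*'s covariance jitter uses stream
#'   `seed + i`; its time-series stream uses `seed + 500000 + i`.
#'
#' @return A list of class `ground_truth_spec`.
#' @seealso [simulate_subject()], [simulate_cohort()], [make_onsets()]
#' @export
ground_truth_spec <- function(n_subjects = 56,
                              n_parcels = 100,
                              network_sizes = c(15L, 15L, 14L, 14L, 14L, 14L, 14L),
                              network_names = c("Default", "Frontoparietal",
                                                "Limbic", "VentralAttention",
                                                "DorsalAttention", "Somatomotor",
                                                "Visual"),
                              r_within = 0.40,
                              r_between = 0.05,
                              subject_jitter_sd = 0.05,
                              ar_coefficient = 0.4,
                              tr_s = 2,
                              rest_duration_s = 480,
                              n_task_runs = 4,
                              task_duration_s = 220,
                              initial_fixation_s = 4,
                              trial_spacing_s = 12,
                              n_trials_per_run = 18,
                              task_amplitude = NULL,
                              evoked_shape = c(0, 0.6, 1, 0.7, 0.3, 0.1),
                              baseline = 1000,
                              confound_sd = 1,
                              confound_loading_sd = 0.1,
                              noise_sd = 0.5,
                              spike_prob = 0.02,
                              spike_magnitude_mm = 1,
                              spike_signal_jump = 3,
                              seed = 1L) {
  network_sizes <- as.integer(network_sizes)
  if (sum(network_sizes) != n_parcels) {
    stop("`network_sizes` must sum to `n_parcels`")
  }
  if (length(network_names) != length(network_sizes)) {
    stop("`network_names` must match `network_sizes` in length")
  }
  if (r_within < 0 || r_within >= 1) stop("`r_within` must be in [0, 1)")
  if (r_between <= -1 || r_between >= 1) stop("`r_between` must be in (-1, 1)")
  if (ar_coefficient < 0 || ar_coefficient >= 1) {
    stop("`ar_coefficient` must be in [0, 1)")
  }
  for (dur in c(rest_duration_s, task_duration_s)) {
    if (abs(dur / tr_s - round(dur / tr_s)) > 1e-9) {
      stop("run durations must be integer multiples of `tr_s`")
    }
  }
  if (initial_fixation_s + (n_trials_per_run - 1L) * trial_spacing_s >=
      task_duration_s) {
    stop("trials do not fit in the task run: last onset exceeds run duration")
  }
  if (is.null(task_amplitude)) {
    responsive <- network_names %in% c("Visual", "DorsalAttention")
    task_amplitude <- rep.int(
      ifelse(responsive, 2.0, 0.3), network_sizes)
  }
  if (length(task_amplitude) == 1L) {
    task_amplitude <- rep(task_amplitude, n_parcels)
  }
  if (length(task_amplitude) != n_parcels) {
    stop("`task_amplitude` must have one entry per parcel")
  }
  spec <- list(
    n_subjects = as.integer(n_subjects), n_parcels = as.integer(n_parcels),
    network_sizes = network_sizes, network_names = network_names,
    r_within = r_within, r_between = r_between,
    subject_jitter_sd = subject_jitter_sd, ar_coefficient = ar_coefficient,
    tr_s = tr_s, rest_duration_s = rest_duration_s,
    n_task_runs = as.integer(n_task_runs), task_duration_s = task_duration_s,
    initial_fixation_s = initial_fixation_s,
    trial_spacing_s = trial_spacing_s,
    n_trials_per_run = as.integer(n_trials_per_run),
    task_amplitude = task_amplitude, evoked_shape = evoked_shape,
    baseline = baseline, confound_sd = confound_sd,
    confound_loading_sd = confound_loading_sd, noise_sd = noise_sd,
    spike_prob = spike_prob, spike_magnitude_mm = spike_magnitude_mm,
    spike_signal_jump = spike_signal_jump, seed = as.integer(seed)
  )
  class(spec) <- "ground_truth_spec"
  spec
}

#' @export
print.ground_truth_spec <- function(x, ...) {
  cat(sprintf(
    "<ground_truth_spec> %d subjects, %d parcels in %d networks\n",
    x$n_subjects, x$n_parcels, length(x$network_sizes)))
  cat(sprintf("  rest %g s + %d task runs of %g s at TR %g s; %d trials/run\n",
              x$rest_duration_s, x$n_task_runs, x$task_duration_s, x$tr_s,
              x$n_trials_per_run))
  cat(sprintf("  r_within %g, r_between %g, jitter sd %g, AR(1) %g, seed %d\n",
              x$r_within, x$r_between, x$subject_jitter_sd,
              x$ar_coefficient, x$seed))
  invisible(x)
}

#' Network label lookup for a spec
#'
#' @param spec A [ground_truth_spec()].
#' @return A data.frame with columns `parcel_id` and `network` (the
#'   atlas-labels table the comparison stage consumes).
#' @export
spec_atlas_labels <- function(spec) {
  data.frame(
    parcel_id = sprintf("p%03d", seq_len(spec$n_parcels)),
    network = rep.int(spec$network_names, spec$network_sizes),
    stringsAsFactors = FALSE
  )
}

#' Subject-specific intrinsic correlation matrix
#'
#' Builds the block-structured true correlation matrix (`r_within` inside
#' network blocks, `r_between` elsewhere), perturbs each off-diagonal entry
#' with subject-specific Gaussian jitter (sd `subject_jitter_sd`), and
#' projects the result to the nearest positive-semidefinite correlation
#' matrix by eigenvalue clipping followed by rescaling to unit diagonal.
#' Deterministic given `(spec$seed, subject_index)`.
#'
#' @param spec A [ground_truth_spec()].
#' @param subject_index Subject number (1-based).
#' @return A `n_parcels` x `n_parcels` correlation matrix (unit diagonal,
#'   symmetric, PSD up to numerical tolerance).
#' @export
make_intrinsic_covariance <- function(spec, subject_index) {
  p <- spec$n_parcels
  net <- rep.int(seq_along(spec$network_sizes), spec$network_sizes)
  same <- outer(net, net, "==")
  m <- ifelse(same, spec$r_within, spec$r_between)
  diag(m) <- 1
  if (spec$subject_jitter_sd > 0) {
    jit <- with_seed(spec$seed + subject_index, {
      j <- matrix(stats::rnorm(p * p, sd = spec$subject_jitter_sd), p, p)
      (j + t(j)) / 2
    })
    diag(jit) <- 0
    m <- m + jit
  }
  nearest_psd_correlation(m)
}

# Eigenvalue clipping at 0, then rescale to unit diagonal. Errors if the
# clipped matrix has a (numerically) zero diagonal entry, i.e. a parcel with
# no admissible variance.
nearest_psd_correlation <- function(m, tol = 1e-8) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= -tol) {
    out <- m
  } else {
    v <- pmax(e$values, 0)
    out <- e$vectors %*% (v * t(e$vectors))
  }
  d <- diag(out)
  if (any(d <= tol)) {
    stop("correlation matrix not repairable: zero variance after PSD projection")
  }
  out <- out / sqrt(d %o% d)
  out <- (out + t(out)) / 2
  diag(out) <- 1
  out
}

#' Trial onset times for a task run
#'
#' Onsets follow the slow event-related design: the first trial starts after
#' `initial_fixation_s` seconds and subsequent trials every `trial_spacing_s`
#' seconds, `n_trials_per_run` in total (defaults: 4, 16, 28, ..., 208 s).
#'
#' @param spec A [ground_truth_spec()].
#' @return Numeric vector of onset times in seconds.
#' @export
make_onsets <- function(spec) {
  onsets <- spec$initial_fixation_s +
    spec$trial_spacing_s * (seq_len(spec$n_trials_per_run) - 1)
  if (max(onsets) >= spec$task_duration_s) {
    stop("trial onsets extend beyond the end of the run")
  }
  onsets
}

#' Simulate one subject
#'
#' Generates the subject's rest run and task runs under the linear
#' superposition model: observed signal = baseline + intrinsic AR(1) process
#' with cross-parcel covariance equal to the subject's true correlation
#' matrix + (task runs only) trial-locked evoked responses + confound
#' contamination + white noise + motion-spike artifacts. Motion parameters
#' are smooth AR(1) drifts with persistent steps at spike volumes.
#'
#' @param spec A [ground_truth_spec()].
#' @param subject_index Subject number (1-based).
#' @return A list of class `synthetic_subject` with elements `subject_id`,
#'   `true_covariance`, `rest_run`, `task_runs` (list), each run holding
#'   `ts` ([parcel_ts()]), `confounds` (data.frame with columns trans_x,
#'   trans_y, trans_z, rot_x, rot_y, rot_z, csf, white_matter,
#'   global_signal), `spike_volumes` (1-based indices), and for task runs
#'   `onsets` (seconds).
#' @export
simulate_subject <- function(spec, subject_index) {
  true_cov <- make_intrinsic_covariance(spec, subject_index)
  # square root via eigendecomposition: valid for semidefinite matrices,
  # which the PSD projection can produce (chol would fail there)
  e <- eigen(true_cov, symmetric = TRUE)
  chol_l <- e$vectors %*% diag(sqrt(pmax(e$values, 0)))
  onsets <- make_onsets(spec)
  with_seed(spec$seed + 500000L + subject_index, {
    loadings <- matrix(stats::rnorm(spec$n_parcels * 3,
                                    sd = spec$confound_loading_sd),
                       spec$n_parcels, 3)
    rest <- simulate_run(spec, chol_l, loadings, task = FALSE,
                         run_id = "task-rest_run-1")
    task_runs <- lapply(seq_len(spec$n_task_runs), function(r) {
      run <- simulate_run(spec, chol_l, loadings, task = TRUE,
                          run_id = sprintf("task-view_run-%d", r))
      run$onsets <- onsets
      run
    })
    structure(
      list(subject_id = sprintf("sub-%02d", subject_index),
           true_covariance = true_cov, rest_run = rest,
           task_runs = task_runs),
      class = "synthetic_subject"
    )
  })
}

# One run: intrinsic + evoked + confounds + noise + spikes. Consumes the
# current RNG stream (callers wrap in with_seed).
simulate_run <- function(spec, chol_l, loadings, task, run_id) {
  dur <- if (task) spec$task_duration_s else spec$rest_duration_s
  n_vol <- as.integer(round(dur / spec$tr_s))
  p <- spec$n_parcels
  phi <- spec$ar_coefficient

  # stationary AR(1) with cross-sectional covariance chol_l %*% t(chol_l)
  innov <- matrix(stats::rnorm(n_vol * p), n_vol, p) %*% t(chol_l)
  innov[-1L, ] <- innov[-1L, ] * sqrt(1 - phi^2)
  intrinsic <- apply(innov, 2L, function(e) {
    as.numeric(stats::filter(e, phi, method = "recursive"))
  })

  sig <- spec$baseline + intrinsic +
    matrix(stats::rnorm(n_vol * p, sd = spec$noise_sd), n_vol, p)

  if (task) {
    onset_vols <- as.integer(round(make_onsets(spec) / spec$tr_s))  # 0-based
    evoked <- matrix(0, n_vol, p)
    k <- length(spec$evoked_shape)
    for (ov in onset_vols) {
      rows <- (ov + 1L):min(ov + k, n_vol)
      evoked[rows, ] <- evoked[rows, ] +
        spec$evoked_shape[seq_along(rows)] %o% spec$task_amplitude
    }
    sig <- sig + evoked
  }

  # physiological confounds: AR(1), marginal sd confound_sd
  physio <- sapply(1:3, function(i) {
    e <- stats::rnorm(n_vol, sd = spec$confound_sd)
    e[-1L] <- e[-1L] * sqrt(1 - 0.5^2)
    as.numeric(stats::filter(e, 0.5, method = "recursive"))
  })
  sig <- sig + physio %*% t(loadings)

  # motion: slow AR(1) drifts around 0; translations mm, rotations radians
  drift <- function(sd_marg) {
    e <- stats::rnorm(n_vol, sd = sd_marg)
    e[-1L] <- e[-1L] * sqrt(1 - 0.95^2)
    as.numeric(stats::filter(e, 0.95, method = "recursive"))
  }
  motion <- cbind(drift(0.05), drift(0.05), drift(0.05),
                  drift(5e-4), drift(5e-4), drift(5e-4))

  # spikes: persistent steps in position and signal at the spike volume
  spike_volumes <- which(stats::runif(n_vol) < spec$spike_prob)
  spike_volumes <- spike_volumes[spike_volumes > 1L]
  for (v in spike_volumes) {
    motion[v:n_vol, 1L] <- motion[v:n_vol, 1L] +
      spec$spike_magnitude_mm * sign(stats::rnorm(1))
    sig[v, ] <- sig[v, ] + stats::rnorm(p, sd = spec$spike_signal_jump)
  }

  confounds <- data.frame(
    trans_x = motion[, 1], trans_y = motion[, 2], trans_z = motion[, 3],
    rot_x = motion[, 4], rot_y = motion[, 5], rot_z = motion[, 6],
    csf = physio[, 1], white_matter = physio[, 2],
    global_signal = physio[, 3]
  )
  list(
    ts = parcel_ts(sig, tr_s = spec$tr_s, run_id = run_id,
                   task = if (task) "task" else "rest"),
    confounds = confounds,
    spike_volumes = as.integer(spike_volumes)
  )
}

#' Simulate a full cohort
#'
#' @param spec A [ground_truth_spec()].
#' @return A list of class `synthetic_cohort`: `spec`, `atlas` (parcel to
#'   network table) and `subjects` (list of [simulate_subject()] results).
#' @export
simulate_cohort <- function(spec) {
  structure(
    list(spec = spec, atlas = spec_atlas_labels(spec),
         subjects = lapply(seq_len(spec$n_subjects),
                           function(i) simulate_subject(spec, i))),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects (seed %d)\n",
              length(x$subjects), x$spec$seed))
  invisible(x)
}

#' Write a cohort to a BIDS-flavored directory tree
#'
#' Lays out, per subject,
#' `sub-XX/ses-1/func/sub-XX_task-{rest,view}_run-N_timeseries.tsv`
#' (volumes x parcels with a parcel-ID header), companion `_confounds.tsv`
#' and, for task runs, `_events.tsv` (onset, duration). The atlas lookup is
#' written once as `atlas_labels.tsv` and the generative parameters as
#' `ground_truth.json` (including each subject's true-covariance file,
#' stored under `truth/`).
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_atlas(cohort$atlas, file.path(dir, "atlas_labels.tsv"))
  truth_dir <- file.path(dir, "truth")
  dir.create(truth_dir, showWarnings = FALSE)
  stim_dur <- 2
  for (sub in cohort$subjects) {
    func <- file.path(dir, sub$subject_id, "ses-1", "func")
    dir.create(func, recursive = TRUE, showWarnings = FALSE)
    stem <- function(run_id, suffix) {
      file.path(func, sprintf("%s_%s_%s.tsv", sub$subject_id, run_id, suffix))
    }
    runs <- c(list(sub$rest_run), sub$task_runs)
    for (run in runs) {
      rid <- run$ts$run_id
      write_timeseries(run$ts, stem(rid, "timeseries"))
      utils::write.table(run$confounds, stem(rid, "confounds"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(run$onsets)) {
        utils::write.table(
          data.frame(onset = run$onsets, duration = stim_dur),
          stem(rid, "events"), sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    cov_path <- file.path(truth_dir,
                          sprintf("%s_true-cov.tsv", sub$subject_id))
    utils::write.table(sub$true_covariance, cov_path, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  spec_out <- cohort$spec
  class(spec_out) <- NULL
  jsonlite::write_json(
    list(spec = spec_out,
         true_covariance_files = file.path(
           "truth", sprintf("%s_true-cov.tsv",
                            vapply(cohort$subjects, `[[`, "", "subject_id")))),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
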