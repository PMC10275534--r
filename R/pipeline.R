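#' Connectivity matrices for a whole cohort
#'
#' Runs the per-run estimation chain on every subject: QC traces from the
#' raw motion parameters and raw parcel series; 100-s high-pass; for task
#' runs, task-evoked activity removed by low-pass filtering ("lpf") and/or
#' FIR residualization ("fir") — "raw" skips removal and is the no-removal
#' control; scrubbing at the FD/DVARS thresholds; nuisance-controlled
#' partial correlations; Fisher z; task runs averaged within subject.
#' Runs flagged for insufficient data after scrubbing are dropped from the
#' average; a subject with no usable task run (or an unusable rest run) is
#' excluded.
#'
#' @param cohort A [simulate_cohort()] or [read_cohort()] result.
#' @param methods Any of `"rest"`, `"lpf"`, `"fir"`, `"raw"`.
#' @param highpass_s,lowpass_s Filter cutoffs (seconds).
#' @param fd_thresh,dvars_thresh,min_retained_frac Scrubbing settings.
#' @param window_trs FIR bins per trial window (default 6).
#' @return A list of class `cohort_connectivity`: `conn` (per method, a
#'   named list of subject-level [conn_matrix()]), `qc` (per subject x run
#'   QC summary data.frame), `excluded` (character), `settings`.
#' @export
cohort_connectivity <- function(cohort,
                                methods = c("rest", "lpf", "fir"),
                                highpass_s = 100, lowpass_s = 16,
                                fd_thresh = 0.5, dvars_thresh = 0.5,
                                min_retained_frac = 0.5,
                                window_trs = 6L) {
  methods <- match.arg(methods, c("rest", "lpf", "fir", "raw"),
                       several.ok = TRUE)
  conn <- stats::setNames(vector("list", length(methods)), methods)
  qc_rows <- list()
  excluded <- character()

  for (sub in cohort$subjects) {
    sid <- sub$subject_id
    res <- try(subject_connectivity(
      sub, methods, highpass_s, lowpass_s, fd_thresh, dvars_thresh,
      min_retained_frac, window_trs), silent = TRUE)
    if (inherits(res, "try-error")) {
      message(sid, " excluded: ", attr(res, "condition")$message)
      excluded <- c(excluded, sid)
      next
    }
    for (m in methods) conn[[m]][[sid]] <- res$conn[[m]]
    qc_rows[[sid]] <- res$qc
  }
  structure(
    list(conn = conn, qc = do.call(rbind, c(qc_rows, make.row.names = FALSE)),
         excluded = excluded,
         settings = list(highpass_s = highpass_s, lowpass_s = lowpass_s,
                         fd_thresh = fd_thresh, dvars_thresh = dvars_thresh,
                         min_retained_frac = min_retained_frac,
                         window_trs = window_trs, methods = methods)),
    class = "cohort_connectivity"
  )
}

subject_connectivity <- function(sub, methods, highpass_s, lowpass_s,
                                 fd_thresh, dvars_thresh, min_retained_frac,
                                 window_trs) {
  sid <- sub$subject_id
  qc_rows <- list()

  process_run <- function(run, series_list) {
    motion <- as.matrix(run$confounds[, c("trans_x", "trans_y", "trans_z",
                                          "rot_x", "rot_y", "rot_z")])
    qc <- qc_trace(motion, run$ts, fd_thresh, dvars_thresh)
    nuis <- build_nuisance(run$confounds)
    out <- list()
    flagged <- FALSE
    for (m in names(series_list)) {
      sc <- withCallingHandlers(
        scrub(series_list[[m]], qc, fd_thresh, dvars_thresh,
              min_retained_frac),
        warning = function(w) invokeRestart("muffleWarning"))
      if (sc$flagged) { flagged <- TRUE; break }
      out[[m]] <- connectivity_matrix(sc$ts, nuis[sc$mask, , drop = FALSE],
                                      method = m, subject_id = sid)
    }
    list(conn = out, flagged = flagged,
         qc = data.frame(subject_id = sid, run_id = run$ts$run_id,
                         task = run$ts$task,
                         mean_fd = mean(qc$fd_mm), max_fd = max(qc$fd_mm),
                         mean_dvars = mean(qc$dvars_pct),
                         max_dvars = max(qc$dvars_pct),
                         retained_frac = mean(qc$mask),
                         stringsAsFactors = FALSE))
  }

  res <- list()
  if ("rest" %in% methods) {
    hp <- highpass(sub$rest_run$ts, highpass_s)
    pr <- process_run(sub$rest_run, list(rest = hp))
    qc_rows[[length(qc_rows) + 1L]] <- pr$qc
    if (pr$flagged) stop("rest run has insufficient data after scrubbing")
    res$rest <- pr$conn$rest
  }
  task_methods <- intersect(methods, c("lpf", "fir", "raw"))
  if (length(task_methods) > 0L) {
    per_run <- list()
    for (run in sub$task_runs) {
      hp <- highpass(run$ts, highpass_s)
      series <- list()
      if ("lpf" %in% task_methods) series$lpf <- lowpass(hp, lowpass_s)
      if ("fir" %in% task_methods) {
        design <- build_fir_design(run$onsets, run$ts$tr_s, nrow(run$ts$data),
                                   window_trs)
        series$fir <- fir_residuals(hp, design, build_nuisance(run$confounds))
      }
      if ("raw" %in% task_methods) series$raw <- hp
      pr <- process_run(run, series)
      qc_rows[[length(qc_rows) + 1L]] <- pr$qc
      if (!pr$flagged) per_run[[length(per_run) + 1L]] <- pr$conn
    }
    if (length(per_run) == 0L) {
      stop("no task run has sufficient data after scrubbing")
    }
    for (m in task_methods) {
      res[[m]] <- average_runs(lapply(per_run, `[[`, m))
    }
  }
  list(conn = res, qc = do.call(rbind, qc_rows))
}

#' Compare rest and background connectivity across a cohort
#'
#' Runs the full comparison battery on the matrices produced by
#' [cohort_connectivity()]:
#' * per-subject fingerprint similarity for each method pair, with a paired
#'   t-test of rest-FIR vs rest-LPF similarity on the Fisher-z scale;
#' * per-subject within/between-network means, the 3 x 2 (method x
#'   connection type) repeated-measures ANOVA with Greenhouse-Geisser
#'   correction, and pairwise follow-ups on the within-minus-between
#'   contrast;
#' * connection-wise and 7 x 7 network-level across-subject stability per
#'   method pair, with summaries and a paired test across connections;
#' * fingerprint-based subject identification accuracy per pair;
#' * association of rest x task similarity with subject-level motion
#'   (mean/max FD and DVARS from the rest run), when QC is supplied.
#'
#' @param cc A [cohort_connectivity()] result (needs methods rest, lpf,
#'   fir), or its `conn` element.
#' @param labels Atlas labels (see [within_between()]).
#' @param qc Optional per subject x run QC data.frame (as in `cc$qc`).
#' @return A list of tidy data.frames and matrices; see Details.
#' @export
compare_cohort <- function(cc, labels, qc = NULL) {
  conn <- if (inherits(cc, "cohort_connectivity")) cc$conn else cc
  if (is.null(qc) && inherits(cc, "cohort_connectivity")) qc <- cc$qc
  needed <- c("rest", "lpf", "fir")
  if (!all(needed %in% names(conn))) {
    stop("compare_cohort needs rest, lpf and fir matrices")
  }
  subjects <- names(conn$rest)
  pairs <- list(rest_lpf = c("rest", "lpf"), rest_fir = c("rest", "fir"),
                lpf_fir = c("lpf", "fir"))

  ## fingerprint similarity
  sim <- do.call(rbind, lapply(names(pairs), function(pn) {
    a <- conn[[pairs[[pn]][1L]]]; b <- conn[[pairs[[pn]][2L]]]
    data.frame(subject_id = subjects, comparison = pn,
               rho = vapply(subjects, function(s) {
                 fingerprint_similarity(a[[s]], b[[s]])
               }, 0), stringsAsFactors = FALSE, row.names = NULL)
  }))
  sim_wide <- stats::reshape(sim, idvar = "subject_id",
                             timevar = "comparison", direction = "wide")
  names(sim_wide) <- sub("^rho\\.", "", names(sim_wide))
  sim_test <- paired_t(fisher_z(sim_wide$rest_fir),
                       fisher_z(sim_wide$rest_lpf))
  sim_test$comparison <- "rest_fir_vs_rest_lpf"

  ## network structure
  wb <- do.call(rbind, lapply(names(conn), function(m) {
    do.call(rbind, lapply(subjects, function(s) {
      v <- within_between(conn[[m]][[s]], labels)
      data.frame(subject_id = s, method = m,
                 connection_type = c("within", "between"),
                 value = unname(v), stringsAsFactors = FALSE)
    }))
  }))
  wb <- wb[wb$method %in% needed, ]
  wb$method <- factor(wb$method, levels = needed)
  anova_tbl <- rm_anova_3x2(wb, subject = "subject_id")
  contrast <- stats::aggregate(
    value ~ subject_id + method,
    data = wb, FUN = function(v) v[1L] - v[2L])   # within - between
  cw <- stats::reshape(contrast, idvar = "subject_id", timevar = "method",
                       direction = "wide")
  names(cw) <- sub("^value\\.", "", names(cw))
  contrast_tests <- rbind(
    cbind(comparison = "lpf_vs_rest", paired_t(cw$lpf, cw$rest)),
    cbind(comparison = "rest_vs_fir", paired_t(cw$rest, cw$fir)),
    cbind(comparison = "lpf_vs_fir", paired_t(cw$lpf, cw$fir)))

  ## stability of individual differences
  stab <- lapply(pairs, function(pr) {
    connectionwise_stability(conn[[pr[1L]]], conn[[pr[2L]]])
  })
  stab_summary <- do.call(rbind, lapply(names(stab), function(pn) {
    cbind(comparison = pn, stability_summary(stab[[pn]]))
  }))
  ok <- !is.na(stab$rest_fir) & !is.na(stab$rest_lpf)
  stab_test <- paired_t(fisher_z(stab$rest_fir[ok]),
                        fisher_z(stab$rest_lpf[ok]))
  stab_test$comparison <- "rest_fir_vs_rest_lpf"
  net_stab <- lapply(pairs, function(pr) {
    network_stability(conn[[pr[1L]]], conn[[pr[2L]]], labels)
  })
  net_stab_summary <- do.call(rbind, lapply(names(net_stab), function(pn) {
    cbind(comparison = pn,
          stability_summary(net_stab[[pn]][upper.tri(net_stab[[pn]],
                                                     diag = TRUE)]))
  }))

  ## identification
  ident <- vapply(pairs, function(pr) {
    identify_subjects(conn[[pr[1L]]], conn[[pr[2L]]])$accuracy
  }, 0)

  ## motion association (rest-run QC)
  motion <- NULL
  if (!is.null(qc)) {
    rest_qc <- qc[qc$task == "rest", , drop = FALSE]
    rest_qc <- rest_qc[match(subjects, rest_qc$subject_id), , drop = FALSE]
    idx <- rest_qc[c("mean_fd", "max_fd", "mean_dvars", "max_dvars")]
    motion <- rbind(
      cbind(comparison = "rest_fir",
            motion_association(sim_wide$rest_fir, idx)),
      cbind(comparison = "rest_lpf",
            motion_association(sim_wide$rest_lpf, idx)))
  }

  list(similarity = sim, similarity_test = sim_test,
       within_between = wb, anova = anova_tbl,
       contrast_tests = contrast_tests,
       stability = stab, stability_summary = stab_summary,
       stability_test = stab_test,
       network_stability = net_stab,
       network_stability_summary = net_stab_summary,
       identification = ident, motion_association = motion)
}

#' Run the end-to-end background-connectivity pipeline
#'
#' Reads a BIDS-flavored tree of parcel time series (as written by
#' [write_cohort()]), computes rest, LPF and FIR connectivity matrices per
#' subject, runs the comparison battery, and writes results under
#' `output_dir`: `conn/` (per-subject matrices, TSV), `compare/` (tidy
#' tables), `stats/` (test results) and `logs/provenance.json` (settings,
#' package version, per-run retained-volume counts, exclusions).
#'
#' @param config A list (or path to nothing — construct in R): elements
#'   `input_dir`, `output_dir`, and optionally `tr_s` (default 2),
#'   `highpass_s` (100), `lowpass_s` (16), `fd_thresh` (0.5),
#'   `dvars_thresh` (0.5), `min_retained_frac` (0.5), `window_trs` (6).
#' @return The [compare_cohort()] result, invisibly, with the
#'   [cohort_connectivity()] object attached as `$connectivity`.
#' @export
run_pipeline <- function(config) {
  defaults <- list(tr_s = 2, highpass_s = 100, lowpass_s = 16,
                   fd_thresh = 0.5, dvars_thresh = 0.5,
                   min_retained_frac = 0.5, window_trs = 6L)
  config <- utils::modifyList(defaults, config)
  if (is.null(config$input_dir) || is.null(config$output_dir)) {
    stop("config needs `input_dir` and `output_dir`")
  }
  cohort <- read_cohort(config$input_dir, tr_s = config$tr_s)
  cc <- cohort_connectivity(
    cohort, methods = c("rest", "lpf", "fir"),
    highpass_s = config$highpass_s, lowpass_s = config$lowpass_s,
    fd_thresh = config$fd_thresh, dvars_thresh = config$dvars_thresh,
    min_retained_frac = config$min_retained_frac,
    window_trs = config$window_trs)
  cmp <- compare_cohort(cc, cohort$atlas)

  out <- config$output_dir
  for (d in c("conn", "compare", "stats", "logs")) {
    dir.create(file.path(out, d), recursive = TRUE, showWarnings = FALSE)
  }
  for (m in names(cc$conn)) {
    for (s in names(cc$conn[[m]])) {
      write_conn_matrix(
        cc$conn[[m]][[s]],
        file.path(out, "conn", sprintf("%s_method-%s_conn.tsv", s, m)))
    }
  }
  wt <- function(df, name) {
    utils::write.table(df, file.path(out, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(cmp$similarity, "compare/similarity.tsv")
  wt(cmp$within_between, "compare/within_between.tsv")
  wt(cmp$stability_summary, "compare/stability_summary.tsv")
  wt(cmp$network_stability_summary, "compare/network_stability_summary.tsv")
  pair_tbl <- upper_pairs(cc$conn$rest[[1L]]$parcel_ids)
  stab_tbl <- cbind(pair_tbl, as.data.frame(cmp$stability))
  wt(stab_tbl, "compare/connection_stability.tsv")
  wt(cmp$anova, "stats/anova.tsv")
  wt(rbind(cbind(test = "similarity", cmp$similarity_test),
           cbind(test = "stability", cmp$stability_test)),
     "stats/paired_tests.tsv")
  wt(cmp$contrast_tests, "stats/contrast_tests.tsv")
  wt(cc$qc, "logs/qc_summary.tsv")
  if (!is.null(cmp$motion_association)) {
    wt(cmp$motion_association, "stats/motion_association.tsv")
  }
  jsonlite::write_json(
    list(settings = cc$settings, config = config,
         package_version = as.character(utils::packageVersion("bgconn")),
         n_subjects = length(cc$conn$rest), excluded = cc$excluded,
         identification = as.list(cmp$identification)),
    file.path(out, "logs", "provenance.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  cmp$connectivity <- cc
  invisible(cmp)
}
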