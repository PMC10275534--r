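#' Paired-samples t-test with generalized eta-squared
#'
#' Two-sided paired t-test: `t = mean(d) / (sd(d) / sqrt(n))` with
#' `df = n - 1`, where `d = x - y`. The effect size is generalized
#' eta-squared for the paired (one within-factor, two-level) design, whose
#' denominator includes the subject sum of squares:
#' `ges = SS_condition / (SS_condition + SS_subject + SS_error)`.
#'
#' @param x,y Paired numeric vectors (same subjects).
#' @return A data.frame row: `statistic`, `df`, `p`, `ges`, `correction`.
#' @examples
#' paired_t(c(1, 2, 3), c(2, 2, 5))
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs")
  d <- x - y
  if (stats::sd(d) == 0) {
    stop("paired t undefined: differences have zero variance")
  }
  tval <- mean(d) / (stats::sd(d) / sqrt(n))
  df <- n - 1L
  p <- 2 * stats::pt(-abs(tval), df)
  # SS decomposition of the 2 x n within design
  grand <- mean(c(x, y))
  ss_cond <- n * sum((c(mean(x), mean(y)) - grand)^2)
  subj_means <- (x + y) / 2
  ss_subj <- 2 * sum((subj_means - grand)^2)
  ss_err <- sum((d - mean(d))^2) / 2
  ges <- ss_cond / (ss_cond + ss_subj + ss_err)
  data.frame(statistic = tval, df = df, p = p, ges = ges,
             correction = "none", stringsAsFactors = FALSE)
}

#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Fully within-subject ANOVA for one or two crossed factors on complete,
#' balanced data. Sums of squares follow the standard cell-mean
#' decomposition with subject as a random factor; each within effect is
#' tested against its own effect-by-subject interaction. Sphericity is
#' handled by the Greenhouse-Geisser epsilon estimated per effect from the
#' covariance matrix of orthonormal contrast scores; degrees of freedom of
#' effects with more than one numerator df are multiplied by epsilon and
#' p-values use the F distribution with the fractional df. Effect sizes
#' are generalized eta-squared with the subject and all error sums of
#' squares in the denominator (the convention for fully within designs).
#'
#' `rm_anova_3x2()` is the 3 (method: rest, lpf, fir) x 2 (connection
#' type: within, between) front-end used by the pipeline;
#' `rm_anova_within()` is the general engine.
#'
#' @param data data.frame in long format.
#' @param dv Name of the dependent-variable column.
#' @param within Character vector of 1 or 2 within-factor column names.
#' @param subject Name of the subject-identifier column.
#' @return data.frame, one row per effect: `effect`, `statistic` (F),
#'   `df1`, `df2` (GG-corrected where applied), `p`, `ges`, `epsilon`,
#'   `correction`.
#' @export
rm_anova_within <- function(data, dv = "value", within, subject = "subject") {
  stopifnot(length(within) %in% 1:2)
  data <- as.data.frame(data)
  for (col in c(dv, within, subject)) {
    if (!col %in% names(data)) stop("column not found: ", col)
  }
  s <- factor(data[[subject]])
  f1 <- factor(data[[within[1L]]])
  f2 <- if (length(within) == 2L) factor(data[[within[2L]]]) else
    factor(rep("1", nrow(data)))
  y <- data[[dv]]
  n <- nlevels(s); a <- nlevels(f1); b <- nlevels(f2)
  counts <- table(s, f1, f2)
  if (any(counts != 1L)) {
    stop("design must be complete and balanced: one observation per cell")
  }
  cell <- array(NA_real_, c(n, a, b))
  cell[cbind(as.integer(s), as.integer(f1), as.integer(f2))] <- y

  g <- mean(cell)
  m_s <- apply(cell, 1L, mean)
  m_a <- apply(cell, 2L, mean)
  m_b <- apply(cell, 3L, mean)
  m_ab <- apply(cell, c(2L, 3L), mean)
  m_as <- apply(cell, c(1L, 2L), mean)
  m_bs <- apply(cell, c(1L, 3L), mean)

  ss_s <- a * b * sum((m_s - g)^2)
  ss_a <- n * b * sum((m_a - g)^2)
  ss_b <- n * a * sum((m_b - g)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, rep(1, b)) -
                      outer(rep(1, a), m_b) + g)^2)
  ss_as <- b * sum((m_as - outer(m_s, rep(1, a)) -
                      outer(rep(1, n), m_a) + g)^2)
  ss_bs <- a * sum((m_bs - outer(m_s, rep(1, b)) -
                      outer(rep(1, n), m_b) + g)^2)
  ss_tot <- sum((cell - g)^2)
  ss_abs <- ss_tot - ss_s - ss_a - ss_b - ss_ab - ss_as - ss_bs

  ss_err_all <- ss_s + ss_as + ss_bs + ss_abs

  one_effect <- function(effect, ss_eff, df1, ss_err, df2, eps) {
    correction <- "none"
    if (df1 > 1L && !is.na(eps)) {
      correction <- "greenhouse_geisser"
      df1 <- df1 * eps
      df2 <- df2 * eps
    }
    # a zero effect SS is an exact null (F = 0) even if the error SS also
    # degenerates to zero (all conditions identical within subject)
    fval <- if (ss_eff <= 1e-12 * max(ss_tot, 1)) 0
    else (ss_eff / df1) / (ss_err / df2)
    data.frame(effect = effect, statistic = fval, df1 = df1, df2 = df2,
               p = stats::pf(fval, df1, df2, lower.tail = FALSE),
               ges = ss_eff / (ss_eff + ss_err_all),
               epsilon = eps, correction = correction,
               stringsAsFactors = FALSE)
  }

  # GG epsilon from the covariance of orthonormal-contrast scores
  gg_eps <- function(scores_matrix, contrasts) {
    if (ncol(contrasts) == 0L) return(NA_real_)
    cs <- scores_matrix %*% contrasts
    v <- stats::cov(cs)
    if (sum(v^2) < 1e-300) return(NA_real_)   # degenerate (constant) scores
    sum(diag(v))^2 / (ncol(v) * sum(v^2))
  }
  orth_contrasts <- function(k) {
    if (k < 2L) return(matrix(0, k, 0L))
    qr.Q(qr(cbind(1, stats::contr.poly(k))))[, -1L, drop = FALSE]
  }
  flat_a <- m_as                      # n x a (averaged over b)
  flat_b <- m_bs                      # n x b
  ca <- orth_contrasts(a)
  cb <- orth_contrasts(b)
  eps_a <- if (a > 1L) gg_eps(flat_a, ca) else NA_real_
  eps_b <- if (b > 1L) gg_eps(flat_b, cb) else NA_real_
  # interaction: contrasts on the n x (a*b) cell matrix
  flat_ab <- matrix(cell, n, a * b)
  eps_ab <- if (a > 1L && b > 1L) {
    gg_eps(flat_ab, kronecker(cb, ca))
  } else NA_real_

  out <- one_effect(within[1L], ss_a, a - 1L, ss_as, (a - 1L) * (n - 1L),
                    if (a > 2L) eps_a else NA_real_)
  if (length(within) == 2L) {
    out <- rbind(
      out,
      one_effect(within[2L], ss_b, b - 1L, ss_bs, (b - 1L) * (n - 1L),
                 if (b > 2L) eps_b else NA_real_),
      one_effect(paste(within, collapse = ":"), ss_ab,
                 (a - 1L) * (b - 1L), ss_abs, (a - 1L) * (b - 1L) * (n - 1L),
                 if ((a - 1L) * (b - 1L) > 1L) eps_ab else NA_real_)
    )
  }
  rownames(out) <- NULL
  out
}

#' @rdname rm_anova_within
#' @export
rm_anova_3x2 <- function(data, dv = "value", subject = "subject") {
  data <- as.data.frame(data)
  for (col in c("method", "connection_type")) {
    if (!col %in% names(data)) stop("column not found: ", col)
  }
  if (nlevels(factor(data$method)) != 3L ||
      nlevels(factor(data$connection_type)) != 2L) {
    stop("expected 3 method levels and 2 connection-type levels")
  }
  rm_anova_within(data, dv = dv, within = c("method", "connection_type"),
                  subject = subject)
}
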