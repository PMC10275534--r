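# Shared fixtures. The medium cohort backs the stochastic acceptance-style
# checks and is built once per test run.

tiny_spec <- function(...) {
  args <- list(n_subjects = 2, n_parcels = 8,
               network_sizes = c(4L, 4L), network_names = c("A", "B"),
               rest_duration_s = 200, n_task_runs = 1, task_duration_s = 220,
               seed = 42L)
  do.call(ground_truth_spec, utils::modifyList(args, list(...)))
}

.fixture_env <- new.env(parent = emptyenv())

# 20 subjects at the default study conditions (100 parcels, 7 networks,
# rest + 4 task runs), with the no-removal "raw" control included.
default_cohort_fixture <- function() {
  if (is.null(.fixture_env$cohort)) {
    spec <- ground_truth_spec(n_subjects = 20, seed = 20260101L)
    cohort <- simulate_cohort(spec)
    cc <- cohort_connectivity(cohort, methods = c("rest", "lpf", "fir", "raw"))
    .fixture_env$cohort <- list(spec = spec, cohort = cohort, cc = cc)
  }
  .fixture_env$cohort
}

# brute-force Spearman: explicit average ranks then Pearson
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# brute-force partial correlation: residualize each column on nuisance by
# explicit normal equations, then Pearson
oracle_partial_corr <- function(y, nuisance = NULL) {
  x <- cbind(1, nuisance)
  beta <- solve(t(x) %*% x, t(x) %*% y)
  stats::cor(y - x %*% beta)
}
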