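test_that("paired t matches the hand-computed oracle and flips sign", {
  x <- c(1, 2, 3); y <- c(2, 2, 5)
  res <- paired_t(x, y)
  d <- x - y                             # -1, 0, -2
  t_oracle <- mean(d) / (sd(d) / sqrt(3))
  expect_equal(res$statistic, t_oracle, tolerance = 1e-12)
  expect_equal(res$df, 2L)
  expect_equal(res$p, 2 * pt(-abs(t_oracle), 2), tolerance = 1e-12)

  flipped <- paired_t(y, x)
  expect_equal(flipped$statistic, -res$statistic, tolerance = 1e-12)
  expect_equal(flipped$p, res$p, tolerance = 1e-12)

  expect_error(paired_t(x, x + 1), "zero variance")
  expect_error(paired_t(1:2, 2:3), "3 pairs")

  # cross-check statistic and p against stats::t.test
  set.seed(20)
  a <- rnorm(12); b <- rnorm(12)
  tt <- t.test(a, b, paired = TRUE)
  got <- paired_t(a, b)
  expect_equal(got$statistic, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(got$p, tt$p.value, tolerance = 1e-12)
})

test_that("two-level RM-ANOVA equals the squared paired t", {
  set.seed(21)
  n <- 9
  df <- data.frame(
    subject = rep(sprintf("s%02d", 1:n), times = 2),
    cond = rep(c("a", "b"), each = n),
    value = rnorm(2 * n))
  fres <- rm_anova_within(df, within = "cond")
  x <- df$value[df$cond == "a"]; y <- df$value[df$cond == "b"]
  tres <- paired_t(x, y)
  expect_equal(fres$statistic, tres$statistic^2, tolerance = 1e-10)
  expect_equal(fres$df2, tres$df)
  expect_equal(fres$p, tres$p, tolerance = 1e-10)
  expect_equal(fres$ges, tres$ges, tolerance = 1e-10)
})

test_that("identical conditions give F = 0 and constants shift nothing", {
  n <- 6
  base <- expand.grid(subject = sprintf("s%d", 1:n),
                      method = c("rest", "lpf", "fir"),
                      connection_type = c("within", "between"))
  base$value <- rnorm(n)[as.integer(base$subject)]  # no condition effect
  res <- rm_anova_3x2(base)
  expect_equal(res$statistic, rep(0, 3), tolerance = 1e-10)

  set.seed(22)
  base$value <- rnorm(nrow(base))
  r1 <- rm_anova_3x2(base)
  base2 <- base; base2$value <- base$value + 100
  r2 <- rm_anova_3x2(base2)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-8)
  expect_equal(r1$ges, r2$ges, tolerance = 1e-8)
})

test_that("3x2 RM-ANOVA SS terms match aov() and epsilon its difference-covariance formula", {
  set.seed(23)
  n <- 6
  df <- expand.grid(subject = sprintf("s%d", 1:n),
                    method = c("rest", "lpf", "fir"),
                    connection_type = c("within", "between"))
  df$value <- rnorm(nrow(df))
  got <- rm_anova_3x2(df)

  fit <- summary(stats::aov(
    value ~ method * connection_type +
      Error(subject / (method * connection_type)), data = df))
  f_of <- function(stratum, term) {
    tab <- fit[[stratum]][[1]]
    tab[trimws(rownames(tab)) == term, "F value"]
  }
  # the GG correction rescales both df by epsilon, so F itself is unchanged
  expect_equal(got$statistic[got$effect == "method"],
               f_of("Error: subject:method", "method"), tolerance = 1e-8)
  expect_equal(got$statistic[got$effect == "connection_type"],
               f_of("Error: subject:connection_type", "connection_type"),
               tolerance = 1e-8)
  expect_equal(got$statistic[got$effect == "method:connection_type"],
               f_of("Error: subject:method:connection_type",
                    "method:connection_type"), tolerance = 1e-8)

  # GG epsilon for the 3-level effect, from the covariance of condition
  # differences (Box): eps = sum(lambda)^2 / ((k-1) * sum(lambda^2))
  wide <- sapply(split(df, df$method), function(d) {
    tapply(d$value, d$subject, mean)
  })
  k <- 3
  s <- cov(wide)
  dbar <- mean(diag(s))
  mbar <- mean(s)
  rowm <- rowMeans(s)
  eps_oracle <- (k * (dbar - mbar))^2 /
    ((k - 1) * (sum(s^2) - 2 * k * sum(rowm^2) + k^2 * mbar^2))
  expect_equal(got$epsilon[got$effect == "method"], eps_oracle,
               tolerance = 1e-8)
  expect_true(all(got$df1 <= c(2, 1, 2) + 1e-9))
  expect_equal(got$correction,
               c("greenhouse_geisser", "none", "greenhouse_geisser"))
})

test_that("GG epsilon stays within its theoretical bounds", {
  set.seed(24)
  for (i in 1:10) {
    n <- sample(5:10, 1)
    df <- expand.grid(subject = sprintf("s%d", 1:n),
                      method = c("m1", "m2", "m3"),
                      connection_type = c("w", "b"))
    df$value <- rnorm(nrow(df))
    res <- rm_anova_3x2(df)
    eps_m <- res$epsilon[res$effect == "method"]
    expect_gte(eps_m, 1 / 2 - 1e-9)     # 1/(k-1), k = 3
    expect_lte(eps_m, 1 + 1e-9)
    eps_i <- res$epsilon[res$effect == "method:connection_type"]
    expect_gte(eps_i, 1 / 2 - 1e-9)
    expect_lte(eps_i, 1 + 1e-9)
  }
})

test_that("unbalanced or incomplete data are rejected", {
  df <- expand.grid(subject = sprintf("s%d", 1:4),
                    method = c("m1", "m2", "m3"),
                    connection_type = c("w", "b"))
  df$value <- rnorm(nrow(df))
  expect_error(rm_anova_3x2(df[-1, ]), "balanced")
  df2 <- df; df2$method <- as.character(df2$method)
  df2$method[1] <- "m4"
  expect_error(rm_anova_3x2(df2), "balanced|3 method")
})
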