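test_that("Anderson-Darling test is calibrated under normality and rejects lognormal data", {
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    anderson_darling(rnorm(500))$p > 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  set.seed(202)
  expect_lt(anderson_darling(rlnorm(200, 0, 1))$p, 0.001)

  # location-scale invariance of the statistic
  set.seed(7)
  x <- rnorm(100)
  expect_equal(anderson_darling(3 + 5 * x)$statistic,
               anderson_darling(x)$statistic)

  expect_true(anderson_darling(rep(1, 20))$degenerate)
  expect_error(anderson_darling(1:5), "n >= 8")
})

test_that("Spearman correlation handles monotone, reversed, and tied inputs", {
  x <- c(1, 2, 3, 4, 5)
  r <- spearman_ci(x, exp(x), n_boot = 50)
  expect_equal(r$rho, 1)
  expect_equal(spearman_ci(c(1, 2, 3), c(2, 1, 0), n_boot = 50)$rho, -1)

  # midrank arithmetic, checked by hand: x ties at 2, y ties at 5
  x <- c(1, 2, 2, 3, 4, 5)
  y <- c(5, 5, 6, 7, 9, 8)
  rx <- c(1, 2.5, 2.5, 4, 5, 6)
  ry <- c(1.5, 1.5, 3, 4, 6, 5)
  hand <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(spearman_ci(x, y, n_boot = 50)$rho, hand)

  expect_true(spearman_ci(rep(1, 5), 1:5, n_boot = 10)$degenerate)

  # rank statistics are invariant under strictly monotone transforms
  set.seed(31)
  a <- rnorm(40); b <- a + rnorm(40)
  expect_equal(spearman_ci(exp(a), b, n_boot = 10)$rho,
               spearman_ci(a, b, n_boot = 10)$rho)
})

test_that("subject-level bootstrap CI brackets the point estimate and respects clustering", {
  set.seed(91)
  subj <- rep(1:20, each = 25)
  prog <- runif(20, 63, 107)[subj]
  y <- 0.3 * scale(prog) + rnorm(500)
  r <- spearman_ci(prog, as.vector(y), subject = subj, n_boot = 400)
  expect_true(r$ci[1] <= r$rho && r$rho <= r$ci[2])
  expect_true(r$ci[1] > 0)  # a real positive association is detected
})

test_that("Mann-Whitney matches the exact enumeration oracle and large-shift power", {
  got <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(got$U, 0)
  expect_equal(got$p, 0.1)  # 2/20 labelings as extreme
  expect_true(got$exact)

  set.seed(47)
  for (rep in 1:20) {
    na <- sample(3:6, 1); nb <- sample(3:6, 1)
    a <- round(rnorm(na, 0, 5), 3); b <- round(rnorm(nb, 1, 5), 3)
    if (anyDuplicated(c(a, b))) next
    expect_equal(mann_whitney(a, b)$p, mw_enum_p(a, b), tolerance = 1e-12)
  }

  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p, 1)

  set.seed(53)
  big <- mann_whitney(rnorm(40), rnorm(40, 10))
  expect_lt(big$p, 0.001)

  # invariance under monotone transforms
  set.seed(59)
  a <- rnorm(8); b <- rnorm(8, 1)
  expect_equal(mann_whitney(exp(a), exp(b))$p, mann_whitney(a, b)$p)
})

test_that("paired Wilcoxon matches sign-flip enumeration and the all-positive configuration", {
  # 9 uniformly positive differences: the smallest attainable two-sided p
  d <- c(5, 8, 13, 2, 7, 11, 3, 9, 6)
  got <- wilcoxon_paired(d)
  expect_true(got$exact)
  expect_equal(got$p, 2 / 2^9)
  expect_equal(round(got$p, 4), 0.0039)

  # antisymmetric differences sit at the null centre
  expect_equal(wilcoxon_paired(c(-3, -2, -1, 1, 2, 3))$p, 1)

  set.seed(61)
  for (rep in 1:20) {
    d <- round(rnorm(6, 0.3, 1), 3)
    d <- d[d != 0]
    if (length(d) < 5 || anyDuplicated(abs(d))) next
    expect_equal(wilcoxon_paired(d)$p, wilcox_enum_p(d), tolerance = 1e-12)
  }

  expect_true(wilcoxon_paired(rep(2, 6), rep(2, 6))$degenerate)
})

test_that("subject records derive expansion status at the 50-repeat threshold", {
  meta <- data.frame(subject_id = c("s1", "s2", "s3"),
                     sampling_age = c(60, 70, 55), sex = c("F", "M", "F"),
                     tissue = "leukocyte",
                     allele_short = c(11, 17, 12),
                     allele_long = c(49, 50, 107))
  rec <- subject_records(meta)
  expect_equal(rec$expansion_status, c("negative", "positive", "positive"))
  expect_error(subject_records(meta[, -2]), "missing column")
})

test_that("log-linear fit recovers a noiseless generating model exactly", {
  d <- simulate_cohort(30, intercept = 5.5, b_progenitor = 0.03,
                       b_age = 0.012, b_interaction = 8e-4, sigma = 0,
                       seed = 5)
  fit <- suppressWarnings(fit_log_linear(d))  # lm warns on a perfect fit
  expect_equal(unname(fit$coefficients),
               c(5.5, 0.03, 0.012, 8e-4), tolerance = 1e-8)
  expect_equal(fit$adj_r_squared, 1, tolerance = 1e-8)
  # residuals orthogonal to each centred predictor
  r <- residuals(fit$fit)
  cp <- d$allele_long - mean(d$allele_long)
  ca <- d$sampling_age - mean(d$sampling_age)
  expect_lt(abs(sum(r * cp)), 1e-6)
  expect_lt(abs(sum(r * ca)), 1e-6)
})

test_that("the interaction coefficient is recovered across simulated cohorts", {
  cover <- vapply(1:50, function(s) {
    d <- simulate_cohort(30, b_interaction = 8e-4, sigma = 0.15, seed = s)
    fit <- fit_log_linear(d)
    se <- summary(fit$fit)$coefficients["cp:ca", "Std. Error"]
    abs(fit$coefficients[["cp:ca"]] - 8e-4) <= 3 * se
  }, logical(1))
  expect_gte(mean(cover), 0.9)
})

test_that("mean centring shrinks the main-effect/interaction collinearity", {
  for (s in 1:10) {
    d <- simulate_cohort(30, sigma = 0.15, seed = s)
    fit <- fit_log_linear(d)
    expect_lt(abs(fit$cor_centred), abs(fit$cor_uncentred))
  }
})

test_that("collinear designs after centring are rejected", {
  d <- simulate_cohort(20, sigma = 0.1, seed = 3)
  d$sampling_age <- d$allele_long  # age duplicates the progenitor predictor
  expect_error(fit_log_linear(d), "collinear")
})
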