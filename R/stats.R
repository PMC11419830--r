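#' Anderson-Darling composite normality test
#'
#' A-squared statistic with the standard small-sample modification and the
#' case-3 (mean and variance estimated) p-value approximation, as
#' implemented in `nortest::ad.test`. Location-scale invariant.
#'
#' @param values Numeric vector, n >= 8.
#' @return List with `statistic` (A^2), `p`, and `degenerate` (`TRUE` for
#'   constant input, in which case the statistic is undefined).
#' @export
anderson_darling <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 8) stop("Anderson-Darling test requires n >= 8")
  if (stats::sd(values) == 0)
    return(list(statistic = NA_real_, p = NA_real_, degenerate = TRUE))
  ht <- nortest::ad.test(values)
  list(statistic = unname(ht$statistic), p = ht$p.value, degenerate = FALSE)
}

#' Spearman rank correlation with bootstrap confidence interval
#'
#' Midrank-based rank correlation. The CI is a percentile bootstrap; when a
#' `subject` grouping is given (e.g. molecule-level observations nested in
#' subjects), whole subjects are resampled so the CI respects the clustered
#' sampling unit.
#'
#' @param x,y Numeric vectors (n >= 3).
#' @param subject Optional grouping vector, same length as `x`.
#' @param n_boot Bootstrap resamples (default 2000).
#' @param conf Confidence level.
#' @return List with `rho`, `ci` (length 2), `n`, `degenerate` (`TRUE` when
#'   either input is constant, in which case `rho` is undefined).
#' @export
spearman_ci <- function(x, y, subject = NULL, n_boot = 2000, conf = 0.95) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, ci = c(NA_real_, NA_real_), n = length(x),
                degenerate = TRUE))
  rho <- stats::cor(x, y, method = "spearman")
  if (is.null(subject)) subject <- seq_along(x)
  groups <- split(seq_along(x), subject)
  reps <- vapply(seq_len(n_boot), function(b) {
    idx <- unlist(groups[sample(length(groups), replace = TRUE)],
                  use.names = FALSE)
    xs <- x[idx]; ys <- y[idx]
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) return(NA_real_)
    stats::cor(xs, ys, method = "spearman")
  }, numeric(1))
  a <- (1 - conf) / 2
  list(rho = rho,
       ci = unname(stats::quantile(reps, c(a, 1 - a), na.rm = TRUE)),
       n = length(x), degenerate = FALSE)
}

#' Mann-Whitney U test (two-sided)
#'
#' Exact null enumeration when the pooled sample size is at most 12 (and no
#' ties are present); otherwise the normal approximation with tie
#' correction.
#'
#' @param group_a,group_b Numeric vectors.
#' @param exact_limit Pooled-size limit for the exact distribution.
#' @return List with `U`, `p`, `exact` (logical).
#' @export
mann_whitney <- function(group_a, group_b, exact_limit = 12) {
  na <- length(group_a); nb <- length(group_b)
  stopifnot(na >= 1, nb >= 1)
  exact <- (na + nb) <= exact_limit && !anyDuplicated(c(group_a, group_b))
  ht <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = exact, correct = TRUE))
  list(U = unname(ht$statistic), p = ht$p.value, exact = exact)
}

#' Wilcoxon matched-pairs signed-rank test (two-sided)
#'
#' Zero differences are dropped (classical convention); the exact null
#' distribution is used for up to 15 non-zero tie-free differences,
#' otherwise the normal approximation. Nine pairs that all move in the same
#' direction give the smallest attainable exact two-sided p, 2/2^9 =
#' 0.0039.
#'
#' @param x,y Paired numeric vectors (per-subject values under the two
#'   conditions), or `y = NULL` with `x` the differences.
#' @param exact_limit Non-zero pair limit for the exact distribution.
#' @return List with `W` (signed-rank statistic), `p`, `n_nonzero`,
#'   `exact`, and `degenerate` (`TRUE` when every difference is zero).
#' @export
wilcoxon_paired <- function(x, y = NULL, exact_limit = 15) {
  d <- if (is.null(y)) x else x - y
  d <- d[d != 0]
  if (length(d) == 0)
    return(list(W = NA_real_, p = NA_real_, n_nonzero = 0L, exact = FALSE,
                degenerate = TRUE))
  if (length(d) < 5)
    warning("fewer than 5 non-zero differences; test poorly powered")
  exact <- length(d) <= exact_limit && !anyDuplicated(abs(d))
  ht <- suppressWarnings(stats::wilcox.test(d, exact = exact, correct = TRUE))
  list(W = unname(ht$statistic), p = ht$p.value,
       n_nonzero = length(d), exact = exact, degenerate = FALSE)
}

#' Build subject records from metadata and per-sample summaries
#'
#' @param metadata Data frame with columns `subject_id`, `sampling_age`,
#'   `sex`, `tissue`, `allele_short`, `allele_long` (progenitor repeat
#'   counts from STR genotyping).
#' @param summaries Optional list of `ogm_sample_summary` (matched by
#'   position) contributing `mean_size`.
#' @param expansion_threshold Expanded-allele definition in repeats
#'   (>= 50).
#' @return Data frame of subject records with `expansion_status` derived
#'   from the long progenitor allele.
#' @export
subject_records <- function(metadata, summaries = NULL,
                            expansion_threshold = 50) {
  req <- c("subject_id", "sampling_age", "tissue", "allele_short", "allele_long")
  miss <- setdiff(req, names(metadata))
  if (length(miss) > 0)
    stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  out <- metadata
  out$expansion_status <- ifelse(out$allele_long >= expansion_threshold,
                                 "positive", "negative")
  if (!is.null(summaries))
    out$mean_size <- vapply(summaries, function(s) s$mean_size, numeric(1))
  out
}

#' Log-linear model of mean molecule size on progenitor size and age
#'
#' Ordinary least squares on `log(mean_size)` with the progenitor
#' long-allele size and (optionally) sampling age as predictors, each
#' mean-centred before the (optional) interaction is formed — centring
#' removes the structural collinearity between a positive-valued main
#' effect and its product term.
#'
#' @param records Data frame with `mean_size` (> 0), `allele_long`, and
#'   `sampling_age`.
#' @param with_age Include the age main effect.
#' @param with_interaction Include the progenitor x age interaction
#'   (implies `with_age`).
#' @return An `ogm_regression`: list with `coefficients`,
#'   `adj_r_squared`, `fit` (the `lm`), and — when the interaction is
#'   present — `cor_uncentred` / `cor_centred`, the correlation between the
#'   progenitor main effect and the interaction column before and after
#'   centring.
#' @export
fit_log_linear <- function(records, with_age = TRUE, with_interaction = TRUE) {
  stopifnot(all(records$mean_size > 0))
  if (with_interaction) with_age <- TRUE
  n_par <- 2 + with_age + with_interaction
  if (nrow(records) < n_par + 3)
    stop("need at least 3 more subjects than parameters")
  d <- data.frame(log_size = log(records$mean_size),
                  cp = records$allele_long - mean(records$allele_long))
  if (with_age) d$ca <- records$sampling_age - mean(records$sampling_age)
  form <- if (with_interaction) log_size ~ cp + ca + cp:ca
          else if (with_age) log_size ~ cp + ca else log_size ~ cp
  fit <- stats::lm(form, data = d)
  if (anyNA(stats::coef(fit)))
    stop("design is collinear after centring")
  out <- list(coefficients = stats::coef(fit),
              adj_r_squared = summary(fit)$adj.r.squared,
              fit = fit)
  if (with_interaction) {
    P <- records$allele_long; A <- records$sampling_age
    out$cor_uncentred <- stats::cor(P, P * A)
    out$cor_centred <- stats::cor(d$cp, d$cp * d$ca)
  }
  structure(out, class = "ogm_regression")
}

#' @export
print.ogm_regression <- function(x, ...) {
  cat("ogm_regression on log(mean_size)\n")
  print(round(x$coefficients, 5))
  cat(sprintf("  adjusted R^2: %.4f\n", x$adj_r_squared))
  if (!is.null(x$cor_centred))
    cat(sprintf("  progenitor/interaction correlation: %.3f uncentred -> %.3f centred\n",
                x$cor_uncentred, x$cor_centred))
  invisible(x)
}

#' Synthetic subject cohort with a known log-linear structure
#'
#' Generates subject-level records whose log mean molecule size follows a
#' specified linear model in centred progenitor size and age (with
#' interaction), for parameter-recovery experiments on the statistical
#' layer. Progenitor long alleles span the expansion-positive range
#' observed in blood (63–107 repeats); ages span typical late-onset
#' sampling ages.
#'
#' @param n_subjects Cohort size.
#' @param intercept,b_progenitor,b_age,b_interaction True coefficients on
#'   the centred scale.
#' @param sigma Residual SD of `log(mean_size)`.
#' @param seed RNG seed.
#' @return Data frame with `subject_id`, `sampling_age`, `sex`, `tissue`,
#'   `allele_short`, `allele_long`, `mean_size`, `expansion_status`.
#' @export
simulate_cohort <- function(n_subjects = 30, intercept = 5.5,
                            b_progenitor = 0.03, b_age = 0.012,
                            b_interaction = 8e-4, sigma = 0.15, seed = 1) {
  set.seed(seed)
  prog <- round(stats::runif(n_subjects, 63, 107))
  age <- round(stats::runif(n_subjects, 50, 85))
  cp <- prog - mean(prog); ca <- age - mean(age)
  log_size <- intercept + b_progenitor * cp + b_age * ca +
    b_interaction * cp * ca + stats::rnorm(n_subjects, 0, sigma)
  data.frame(subject_id = sprintf("S%02d", seq_len(n_subjects)),
             sampling_age = age,
             sex = sample(c("F", "M"), n_subjects, replace = TRUE),
             tissue = "leukocyte",
             allele_short = round(stats::runif(n_subjects, 11, 33)),
             allele_long = prog,
             mean_size = exp(log_size),
             expansion_status = ifelse(prog >= 50, "positive", "negative"))
}
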