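# Before/after growth statistics: paired and two-sample t tests assembled
# from first principles (t statistic by formula, p values through the
# incomplete-beta relation of the t distribution), plus the mean +/- SEM
# and gainer-percentage group summaries used for cohort reporting.

# Two-sided tail probability of |T| >= |t| under a t distribution with df
# degrees of freedom, via P(|T| >= t) = I_{df/(df+t^2)}(df/2, 1/2).
tTailTwoSided <- function(t, df) {
  stats::pbeta(df / (df + t^2), df / 2, 0.5)
}

# CDF of the t distribution through the same relation (used by tests to
# compare against an independent reference on a grid).
tCdf <- function(t, df) {
  half <- tTailTwoSided(t, df) / 2
  ifelse(t >= 0, 1 - half, half)
}

#' Paired t test on before/after weights
#'
#' Student's t test for paired samples: with differences
#' \eqn{d_i = \mathrm{after}_i - \mathrm{before}_i},
#' \eqn{t = \bar d / (s_d / \sqrt n)} on \eqn{n - 1} degrees of freedom,
#' two-sided p value from the incomplete-beta relation of the t
#' distribution.
#'
#' @param before,after numeric vectors of equal length (>= 2), e.g. weights
#'   at the start and end of a trial.
#' @return a [PairedTestResult-class].
#' @section Errors: differences with zero variance (all equal, e.g. a pure
#'   constant shift measured without noise) raise a degenerate-variance
#'   error; unequal lengths are rejected.
#' @examples
#' pairedTtest(c(1, 2, 3), c(2, 2, 5))  # t = sqrt(3), df = 2
#' @export
pairedTtest <- function(before, after) {
  if (length(before) != length(after))
    stop("before and after must have equal length", call. = FALSE)
  n <- length(before)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- after - before
  sdd <- stats::sd(d)
  if (sdd == 0)
    stop("degenerate variance: all paired differences are identical",
         call. = FALSE)
  sem <- sdd / sqrt(n)
  t <- mean(d) / sem
  df <- n - 1
  new("PairedTestResult", meanDifference = mean(d), semDifference = sem,
      tStatistic = t, degreesOfFreedom = df,
      pValue = tTailTwoSided(t, df))
}

#' Two-sample t test on group increments
#'
#' Compares the means of two independent samples (typically per-fish weight
#' increments of two husbandry groups). The default is Welch's test with
#' Satterthwaite degrees of freedom; \code{equalVariance = TRUE} selects
#' the pooled-variance variant. Both agree exactly when group sizes and
#' variances are equal.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param equalVariance use the pooled-variance variant.
#' @return a [TwoSampleTestResult-class].
#' @export
twosampleTtest <- function(a, b, equalVariance = FALSE) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0)
    stop("degenerate variance in both groups", call. = FALSE)
  if (equalVariance) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
    method <- "pooled"
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    method <- "welch"
  }
  t <- (mean(a) - mean(b)) / se
  new("TwoSampleTestResult", meanDifference = mean(a) - mean(b),
      tStatistic = t, degreesOfFreedom = df,
      pValue = tTailTwoSided(t, df), method = method)
}

#' Summarize a group of weights or increments
#'
#' Mean, standard error of the mean (sd / sqrt(n); \code{NA} for a single
#' observation) and the gainer percentage: the share of strictly positive
#' values, rounded to two decimals. The gainer percentage is meaningful
#' when the input is a vector of weight increments.
#'
#' @param x numeric vector, length >= 1.
#' @return a [GroupSummary-class].
#' @examples
#' summarizeGroup(c(rep(1, 8), rep(-1, 7)))  # gainers 53.33%
#' @export
summarizeGroup <- function(x) {
  if (length(x) == 0L) stop("empty input", call. = FALSE)
  n <- length(x)
  new("GroupSummary", n = n, mean = mean(x),
      sem = if (n > 1L) stats::sd(x) / sqrt(n) else NA_real_,
      gainerPercent = round(100 * sum(x > 0) / n, 2))
}

#' Full cohort analysis
#'
#' Convenience wrapper over the module's primitives for a before/after
#' cohort table: per-group summaries of initial weight, final weight and
#' increment; a paired t test of final vs initial weight within each group;
#' and a two-sample comparison (Welch by default) of the increments between
#' the two groups. No multiple-testing correction is applied.
#'
#' @param cohort data.frame in the cohort schema (see [readCohortTable()]).
#' @param equalVariance passed to [twosampleTtest()].
#' @return nested list: \code{groups} (per group: \code{t0}, \code{t1},
#'   \code{delta} summaries and \code{paired} test) and
#'   \code{increment_comparison}.
#' @export
analyzeCohort <- function(cohort, equalVariance = FALSE) {
  stopifnot(all(c("group", "weight_t0_kg", "weight_t1_kg") %in% names(cohort)))
  groups <- unique(cohort$group)
  res <- lapply(groups, function(g) {
    d <- cohort[cohort$group == g, ]
    delta <- d$weight_t1_kg - d$weight_t0_kg
    list(t0 = summarizeGroup(d$weight_t0_kg),
         t1 = summarizeGroup(d$weight_t1_kg),
         delta = summarizeGroup(delta),
         paired = pairedTtest(d$weight_t0_kg, d$weight_t1_kg))
  })
  names(res) <- groups
  cmp <- if (length(groups) == 2L) {
    da <- cohort[cohort$group == groups[1], ]
    db <- cohort[cohort$group == groups[2], ]
    twosampleTtest(da$weight_t1_kg - da$weight_t0_kg,
                   db$weight_t1_kg - db$weight_t0_kg,
                   equalVariance = equalVariance)
  } else NULL
  list(groups = res, increment_comparison = cmp)
}

#' Flatten a cohort analysis into a JSON-friendly list
#'
#' @param stats result of [analyzeCohort()].
#' @return nested list of plain numbers, suitable for
#'   \code{jsonlite::write_json}.
#' @export
cohortStatsAsList <- function(stats) {
  gs <- lapply(stats$groups, function(g)
    list(t0 = list(n = g$t0@n, mean = g$t0@mean, sem = g$t0@sem),
         t1 = list(n = g$t1@n, mean = g$t1@mean, sem = g$t1@sem),
         delta = list(n = g$delta@n, mean = g$delta@mean, sem = g$delta@sem,
                      gainer_percent = g$delta@gainerPercent),
         paired = list(t = g$paired@tStatistic,
                       df = g$paired@degreesOfFreedom,
                       p = g$paired@pValue)))
  cmp <- stats$increment_comparison
  list(groups = gs,
       increment_comparison = if (is.null(cmp)) NULL
       else list(method = cmp@method, t = cmp@tStatistic,
                 df = cmp@degreesOfFreedom, p = cmp@pValue))
}
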