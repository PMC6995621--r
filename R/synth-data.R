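# Synthetic morphometric and cohort tables.

#' Generate a synthetic allometric morphometry table
#'
#' Draws body lengths uniformly, widths as length times a uniform aspect
#' ratio, and weights from the power law
#' \eqn{W = \alpha L^{\beta} w^{\gamma} e^{\epsilon}} with
#' \eqn{\epsilon \sim N(0, \log(1 + \mathrm{noiseCv}))}. With
#' \code{noiseCv = 0} the records lie exactly on the power-law surface, so a
#' log-log least-squares fit recovers the generating coefficients to
#' machine precision.
#'
#' @param n number of records (default 400, the size of the morphometric
#'   training table the regressor is built from).
#' @param alpha,beta,gamma power-law coefficients; defaults match
#'   [defaultAllometricWeight()].
#' @param noiseCv relative (lognormal) weight noise; 0 for noise-free data.
#' @param seed RNG seed.
#' @param lengthRangeCm uniform sampling range of body length in cm.
#' @param aspectRange uniform range of the width/length ratio.
#' @param lengths,widths optional explicit dimension vectors (recycled
#'   checks apply); when given they override the random draws and \code{n}
#'   must equal their length.
#' @return data.frame with columns \code{length_cm}, \code{width_cm},
#'   \code{weight_g}.
#' @examples
#' head(generateBiomassDataset(n = 5, seed = 1))
#' @export
generateBiomassDataset <- function(n = 400, alpha = 750 / (35^2 * 14),
                                   beta = 2, gamma = 1, noiseCv = 0.05,
                                   seed = 1L, lengthRangeCm = c(20, 40),
                                   aspectRange = c(0.30, 0.50),
                                   lengths = NULL, widths = NULL) {
  if (n < 2) stop("need at least n = 2 records", call. = FALSE)
  if (alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (noiseCv < 0) stop("noiseCv must be >= 0", call. = FALSE)
  withSeed(seed, {
    if (is.null(lengths))
      lengths <- stats::runif(n, lengthRangeCm[1], lengthRangeCm[2])
    if (is.null(widths))
      widths <- lengths * stats::runif(n, aspectRange[1], aspectRange[2])
    if (length(lengths) != n || length(widths) != n)
      stop("lengths and widths must have length n", call. = FALSE)
    eps <- if (noiseCv > 0) stats::rnorm(n, 0, log1p(noiseCv)) else 0
    data.frame(length_cm = lengths, width_cm = widths,
               weight_g = alpha * lengths^beta * widths^gamma * exp(eps))
  })
}

#' Generate a synthetic before/after growth cohort
#'
#' Two groups (CTRL and EXP) of \code{nPerGroup} fish each, split over three
#' tank replicates, sharing one initial-weight distribution. Final weights
#' follow \code{weight_t1 = weight_t0 * (1 + effect + noise)} with a
#' group-specific multiplicative growth effect and Gaussian relative noise.
#'
#' @param nPerGroup fish per group; must be divisible by 3 (replicates).
#' @param meanT0Kg,sdT0Kg initial weight distribution (kg); defaults emulate
#'   adult soles around 0.75 kg.
#' @param growthEffectCtrl,growthEffectExp mean relative weight gain of the
#'   control and experimental group over the trial.
#' @param noiseSd sd of the individual relative growth noise.
#' @param seed RNG seed.
#' @return data.frame with columns \code{fish_id}, \code{group},
#'   \code{replicate}, \code{sex}, \code{weight_t0_kg}, \code{weight_t1_kg}.
#' @examples
#' head(generateGrowthCohort(seed = 1))
#' @export
generateGrowthCohort <- function(nPerGroup = 15, meanT0Kg = 0.75,
                                 sdT0Kg = 0.35, growthEffectCtrl = 0.025,
                                 growthEffectExp = 0.11, noiseSd = 0.05,
                                 seed = 1L) {
  if (nPerGroup %% 3 != 0)
    stop("nPerGroup must be divisible by 3 (three tank replicates)",
         call. = FALSE)
  if (meanT0Kg <= 0) stop("meanT0Kg must be > 0", call. = FALSE)
  if (sdT0Kg < 0 || noiseSd < 0) stop("sds must be >= 0", call. = FALSE)
  withSeed(seed, {
    n <- 2L * nPerGroup
    t0 <- stats::rnorm(n, meanT0Kg, sdT0Kg)
    while (any(t0 <= 0.01))                      # weights must stay positive
      t0[t0 <= 0.01] <- stats::rnorm(sum(t0 <= 0.01), meanT0Kg, sdT0Kg)
    group <- rep(c("CTRL", "EXP"), each = nPerGroup)
    effect <- ifelse(group == "CTRL", growthEffectCtrl, growthEffectExp)
    noise <- if (noiseSd > 0) stats::rnorm(n, 0, noiseSd) else 0
    t1 <- t0 * (1 + effect + noise)
    t1 <- pmax(t1, 0.01)
    data.frame(fish_id = sprintf("%s-%02d", group, rep(seq_len(nPerGroup), 2)),
               group = group,
               replicate = rep(rep(1:3, each = nPerGroup / 3), 2),
               sex = sample(c("M", "F", "unknown"), n, replace = TRUE,
                            prob = c(0.45, 0.45, 0.10)),
               weight_t0_kg = t0, weight_t1_kg = t1)
  })
}

#' Read and write the package's CSV tables
#'
#' Morphometry tables use the header \code{length_cm,width_cm,weight_g};
#' cohort tables use \code{fish_id,group,replicate,sex,weight_t0_kg,
#' weight_t1_kg}. Numeric columns are written at full double precision so a
#' round trip reproduces the table exactly.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return \code{readBiomassTable} / \code{readCohortTable} return the
#'   validated data.frame; the writers return \code{path} invisibly.
#' @name tableIO
NULL

.writeTable <- function(x, path) {
  num <- vapply(x, is.numeric, logical(1))
  x[num] <- lapply(x[num], function(v) sprintf("%.17g", v))
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname tableIO
#' @export
writeBiomassTable <- function(x, path) {
  stopifnot(all(c("length_cm", "width_cm", "weight_g") %in% names(x)))
  .writeTable(x[c("length_cm", "width_cm", "weight_g")], path)
}

#' @rdname tableIO
#' @export
readBiomassTable <- function(path) {
  x <- utils::read.csv(path)
  if (!all(c("length_cm", "width_cm", "weight_g") %in% names(x)))
    stop("not a morphometry table (need length_cm,width_cm,weight_g)",
         call. = FALSE)
  x
}

.cohortCols <- c("fish_id", "group", "replicate", "sex",
                 "weight_t0_kg", "weight_t1_kg")

#' @rdname tableIO
#' @export
writeCohortTable <- function(x, path) {
  stopifnot(all(.cohortCols %in% names(x)))
  .writeTable(x[.cohortCols], path)
}

#' @rdname tableIO
#' @export
readCohortTable <- function(path) {
  x <- utils::read.csv(path)
  if (!all(.cohortCols %in% names(x)))
    stop("not a cohort table (need ", paste(.cohortCols, collapse = ","), ")",
         call. = FALSE)
  if (any(x$weight_t0_kg <= 0) || any(x$weight_t1_kg <= 0))
    stop("cohort weights must be positive", call. = FALSE)
  x
}
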