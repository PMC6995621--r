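# Phase 4: the dimensions-to-weight regressor. A nine-layer fully connected
# network trained with adam (learning rate 0.001, batch size 4) on
# standardized inputs and standardized log-weight, plus a closed-form
# allometric baseline fitted by log-log least squares that serves as oracle
# and fallback.

.mlpHidden <- c(64L, 64L, 32L, 32L, 16L, 16L, 8L)

#' Fit the closed-form allometric baseline
#'
#' Ordinary least squares of \code{log(weight_g)} on \code{log(length_cm)}
#' and \code{log(width_cm)}: the standard length-weight power law extended
#' with body width. On noise-free power-law data the generating
#' coefficients are recovered to machine precision.
#'
#' @param records data.frame with positive columns \code{length_cm},
#'   \code{width_cm}, \code{weight_g}; at least 3 rows.
#' @return named numeric(3): \code{log_alpha}, \code{beta}, \code{gamma}.
#' @section Errors: a rank-deficient design (e.g. all lengths identical)
#'   raises a degenerate-fit error.
#' @export
fitAllometricBaseline <- function(records) {
  if (nrow(records) < 3L) stop("need at least 3 records", call. = FALSE)
  if (any(records$length_cm <= 0) || any(records$width_cm <= 0) ||
      any(records$weight_g <= 0))
    stop("all dimensions and weights must be positive", call. = FALSE)
  d <- data.frame(lw = log(records$weight_g), ll = log(records$length_cm),
                  lg = log(records$width_cm))
  fit <- stats::lm(lw ~ ll + lg, data = d)
  cf <- stats::coef(fit)
  if (fit$rank < 3L || anyNA(cf))
    stop("degenerate fit: design is rank-deficient (dimensions carry no independent variation)",
         call. = FALSE)
  c(log_alpha = unname(cf[1]), beta = unname(cf["ll"]),
    gamma = unname(cf["lg"]))
}

#' Build a baseline-only biomass model
#'
#' Wraps allometric coefficients as a [BiomassModel-class] usable with
#' [predictWeight()]: \eqn{W = e^{\log\alpha} L^{\beta} w^{\gamma}}.
#'
#' @param logAlpha,beta,gamma power-law coefficients (natural log of the
#'   scale coefficient, length exponent, width exponent); defaults are the
#'   package's ground-truth relationship ([defaultAllometricWeight()]).
#' @return a [BiomassModel-class] of type \code{"baseline"}.
#' @export
allometricBiomassModel <- function(logAlpha = log(750 / (35^2 * 14)),
                                   beta = 2, gamma = 1) {
  new("BiomassModel", type = "baseline", architecture = integer(),
      activation = "relu", weights = list(), biases = list(),
      xCenter = numeric(2), xScale = c(1, 1), yCenter = 0, yScale = 1,
      baseline = c(log_alpha = logAlpha, beta = beta, gamma = gamma),
      trainingRange = matrix(c(0, Inf, 0, Inf), 2, 2,
                             dimnames = list(c("min", "max"),
                                             c("length_cm", "width_cm"))),
      trained = TRUE, metadata = list(optimizer = "none"))
}

#' Train the nine-layer biomass network
#'
#' Fits the dimensions-to-weight regressor on a morphometry table: inputs
#' (length, width) are standardized, the target is standardized log-weight
#' (matching the multiplicative error structure of allometry), and the
#' network (layer widths 2-64-64-32-32-16-16-8-1, ReLU hidden activations,
#' linear output) is trained by mini-batch adam with mean-squared-error
#' loss. Optimizer defaults are learning rate 0.001 and batch size 4.
#' Training stops after \code{epochs} epochs or once the mean epoch loss
#' has not improved for \code{patience} epochs. The allometric baseline is
#' fitted on the same training split and stored in the model.
#'
#' @param records data.frame with columns \code{length_cm}, \code{width_cm},
#'   \code{weight_g}; at least 20 rows, weights strictly positive.
#' @param epochs maximum training epochs.
#' @param splitFraction fraction of records used for training; the rest is
#'   the held-out test set.
#' @param learningRate adam learning rate.
#' @param batchSize mini-batch size.
#' @param seed RNG seed driving the split, the initialization and the
#'   batch order; the same seed reproduces the trained weights exactly.
#' @param patience early-stopping patience in epochs.
#' @param hidden integer vector of hidden-layer widths.
#' @return list with \code{model} (a trained [BiomassModel-class]) and
#'   \code{report} (a [FitReport-class] with held-out R-squared and RMSE on
#'   the gram scale).
#' @export
fitBiomassMlp <- function(records, epochs = 2000L, splitFraction = 0.8,
                          learningRate = 0.001, batchSize = 4L, seed = 1L,
                          patience = 100L, hidden = .mlpHidden) {
  if (nrow(records) < 20L) stop("need at least 20 records", call. = FALSE)
  if (any(records$weight_g <= 0))
    stop("weights must be strictly positive", call. = FALSE)
  if (any(records$length_cm <= 0) || any(records$width_cm <= 0))
    stop("dimensions must be strictly positive", call. = FALSE)

  n <- nrow(records)
  idx <- withSeed(seed, sample.int(n))
  nTrain <- max(2L, floor(splitFraction * n))
  trainIdx <- idx[seq_len(nTrain)]
  testIdx <- if (nTrain < n) idx[(nTrain + 1L):n] else integer()

  # Inputs enter the network as standardized log-dimensions and the target
  # as standardized log-weight: allometric growth is log-linear, so the
  # network fits a nearly linear map and stays well behaved at the edges of
  # the training range.
  Xall <- log(as.matrix(records[, c("length_cm", "width_cm")]))
  yall <- log(records$weight_g)
  xc <- colMeans(Xall[trainIdx, , drop = FALSE])
  xs <- apply(Xall[trainIdx, , drop = FALSE], 2L, stats::sd)
  xs[xs == 0 | is.na(xs)] <- 1
  yc <- mean(yall[trainIdx])
  ys <- stats::sd(yall[trainIdx])
  if (is.na(ys) || ys == 0) ys <- 1
  Xs <- sweep(sweep(Xall, 2L, xc), 2L, xs, `/`)
  yz <- (yall - yc) / ys

  arch <- as.integer(c(2L, hidden, 1L))
  fit <- mlpTrain(Xs[trainIdx, , drop = FALSE], yz[trainIdx], arch,
                  learningRate = learningRate, batchSize = batchSize,
                  epochs = epochs, seed = seed, patience = patience)

  baseline <- tryCatch(fitAllometricBaseline(records[trainIdx, , drop = FALSE]),
                       error = function(e) c(log_alpha = NA_real_,
                                             beta = NA_real_,
                                             gamma = NA_real_))

  dims <- as.matrix(records[trainIdx, c("length_cm", "width_cm")])
  rng <- rbind(min = apply(dims, 2L, min), max = apply(dims, 2L, max))
  model <- new("BiomassModel", type = "mlp", architecture = arch,
               activation = "relu", weights = fit$params$W,
               biases = fit$params$b, xCenter = xc, xScale = xs,
               yCenter = yc, yScale = ys, baseline = baseline,
               trainingRange = rng, trained = TRUE,
               metadata = list(optimizer = "adam",
                               learning_rate = learningRate,
                               batch_size = as.integer(batchSize),
                               epochs_run = length(fit$lossTrace),
                               seed = as.integer(seed),
                               split_fraction = splitFraction))

  predG <- function(ii) predictWeight(model, records$length_cm[ii],
                                      records$width_cm[ii], warn = FALSE)
  obsTr <- records$weight_g[trainIdx]
  prTr <- predG(trainIdx)
  if (length(testIdx)) {
    obsTe <- records$weight_g[testIdx]
    prTe <- predG(testIdx)
    testR2 <- evaluateR2(prTe, obsTe)
    testRmse <- sqrt(mean((prTe - obsTe)^2))
  } else {
    testR2 <- NA_real_
    testRmse <- NA_real_
  }
  report <- new("FitReport", trainR2 = evaluateR2(prTr, obsTr),
                testR2 = testR2,
                trainRmseG = sqrt(mean((prTr - obsTr)^2)),
                testRmseG = testRmse, lossTrace = fit$lossTrace,
                nTrain = length(trainIdx), nTest = length(testIdx))
  list(model = model, report = report)
}

#' Predict individual fish weight from body dimensions
#'
#' @param model a trained [BiomassModel-class] (network or baseline).
#' @param lengthCm,widthCm body dimensions in cm; vectorized.
#' @param warn emit an extrapolation warning when an input lies outside the
#'   training range by more than 25 percent.
#' @return predicted weight(s) in grams; always finite and positive.
#' @examples
#' m <- allometricBiomassModel(log(0.01), 2, 1)
#' predictWeight(m, 20, 8)  # 32
#' @export
predictWeight <- function(model, lengthCm, widthCm, warn = TRUE) {
  stopifnot(is(model, "BiomassModel"))
  if (!model@trained) stop("model is not trained", call. = FALSE)
  if (any(lengthCm <= 0) || any(widthCm <= 0))
    stop("dimensions must be strictly positive", call. = FALSE)
  if (length(widthCm) != length(lengthCm))
    stop("lengthCm and widthCm must have equal length", call. = FALSE)
  if (model@type == "baseline") {
    b <- model@baseline
    return(exp(b[["log_alpha"]]) * lengthCm^b[["beta"]] * widthCm^b[["gamma"]])
  }
  rng <- model@trainingRange
  span <- rng["max", ] - rng["min", ]
  lo <- rng["min", ] - 0.25 * span
  hi <- rng["max", ] + 0.25 * span
  if (warn && (any(lengthCm < lo[1] | lengthCm > hi[1]) ||
               any(widthCm < lo[2] | widthCm > hi[2])))
    warning("input dimensions lie > 25% outside the training range; prediction is an extrapolation",
            call. = FALSE)
  X <- log(cbind(lengthCm, widthCm))
  Xs <- sweep(sweep(X, 2L, model@xCenter), 2L, model@xScale, `/`)
  yz <- mlpPredict(list(W = model@weights, b = model@biases), Xs)
  exp(yz * model@yScale + model@yCenter)
}

#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - SS_{res} / SS_{tot}}. When the observed values are
#' constant (\eqn{SS_{tot} = 0}) the convention is 1 for a perfect fit and
#' 0 otherwise.
#'
#' @param predicted,observed numeric vectors of equal length (>= 2).
#' @return scalar R-squared (at most 1; unbounded below).
#' @examples
#' evaluateR2(c(1, 2, 4), c(1, 2, 3))  # 0.5
#' @export
evaluateR2 <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("predicted and observed must have equal length", call. = FALSE)
  if (length(observed) < 2L) stop("need at least 2 values", call. = FALSE)
  ssRes <- sum((observed - predicted)^2)
  ssTot <- sum((observed - mean(observed))^2)
  if (ssTot == 0) return(if (ssRes == 0) 1 else 0)
  1 - ssRes / ssTot
}

#' Save and load a biomass model as versioned JSON
#'
#' The full model state (architecture, weights, standardization, baseline,
#' metadata) is serialized at full double precision, so a round trip
#' reproduces predictions bit for bit.
#'
#' @param model a [BiomassModel-class].
#' @param path JSON file path.
#' @return \code{readBiomassModel} returns the model; the writer returns
#'   \code{path} invisibly.
#' @name modelIO
NULL

#' @rdname modelIO
#' @export
writeBiomassModel <- function(model, path) {
  stopifnot(is(model, "BiomassModel"))
  doc <- list(format = "soleVision-biomass-model", version = 1L,
              type = model@type,
              architecture = model@architecture,
              activation = model@activation,
              weights = lapply(model@weights, function(w)
                list(dim = dim(w), data = as.numeric(w))),
              biases = model@biases,
              x_center = model@xCenter, x_scale = model@xScale,
              y_center = model@yCenter, y_scale = model@yScale,
              baseline = as.list(model@baseline),
              training_range = list(min = model@trainingRange["min", ],
                                    max = model@trainingRange["max", ]),
              trained = model@trained, metadata = model@metadata)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname modelIO
#' @export
readBiomassModel <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "soleVision-biomass-model"))
    stop("not a biomass model file", call. = FALSE)
  num <- function(x) vapply(x, as.numeric, numeric(1))
  w <- lapply(doc$weights, function(wi)
    matrix(num(wi$data), wi$dim[[1]], wi$dim[[2]]))
  b <- lapply(doc$biases, num)
  rng <- rbind(min = num(doc$training_range$min),
               max = num(doc$training_range$max))
  colnames(rng) <- c("length_cm", "width_cm")
  new("BiomassModel", type = doc$type,
      architecture = as.integer(doc$architecture),
      activation = doc$activation, weights = w, biases = b,
      xCenter = as.numeric(doc$x_center), xScale = as.numeric(doc$x_scale),
      yCenter = as.numeric(doc$y_center), yScale = as.numeric(doc$y_scale),
      baseline = c(log_alpha = doc$baseline$log_alpha,
                   beta = doc$baseline$beta, gamma = doc$baseline$gamma),
      trainingRange = rng, trained = isTRUE(doc$trained),
      metadata = as.list(doc$metadata))
}
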