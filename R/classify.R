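#' Fit a per-feature standardizer on training data
#'
#' Each feature is centered to mean 0 and scaled to unit variance, the
#' statistics being estimated on the training rows only. The scale is the
#' population (n-divisor) standard deviation, so two training values `(0, 2)`
#' map to exactly `(-1, +1)`. Zero-variance features get scale 1 so they map
#' to exactly 0 and never divide by zero.
#'
#' @param x numeric training matrix, one row per clip, one column per
#'   feature.
#' @return A [FeatureNormalizer-class].
#' @export
fitNormalizer <- function(x) {
  x <- as.matrix(x)
  if (!nrow(x)) stop("cannot fit a normalizer on an empty matrix")
  ctr <- colMeans(x)
  sds <- sqrt(colMeans(sweep(x, 2L, ctr)^2))
  sds[!is.finite(sds) | sds == 0] <- 1
  new("FeatureNormalizer", center = ctr, scale = sds)
}

#' Apply a fitted standardizer
#'
#' @param normalizer a [FeatureNormalizer-class].
#' @param x numeric matrix with the same feature columns as at fitting.
#' @return The standardized matrix.
#' @export
applyNormalizer <- function(normalizer, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(normalizer@center))
    stop("feature count does not match the fitted normalizer")
  scale(x, center = normalizer@center, scale = normalizer@scale)[, ,
    drop = FALSE]
}

#' Train an activity classifier
#'
#' Two families are supported. `svm_rbf` is a soft-margin support vector
#' machine with radial basis kernel `exp(-gamma * ||u - v||^2)`, multiclass
#' via one-vs-one (the libsvm convention). `smlr` is sparse multinomial
#' logistic regression: the multinomial log-likelihood penalized by
#' `lambda * ||coefficients||_1`, which drives irrelevant feature weights to
#' exactly zero.
#'
#' Features are expected already standardized (see [fitNormalizer()]); no
#' scaling happens here so that training-fold statistics never leak into
#' test folds.
#'
#' @param spec a [ClassifierSpec-class].
#' @param x numeric feature matrix, one row per clip.
#' @param labels activity labels, one per row, at least 2 distinct.
#' @return An [ActivityModel-class].
#' @export
trainClassifier <- function(spec, x, labels) {
  stopifnot(is(spec, "ClassifierSpec"))
  x <- as.matrix(x)
  y <- asActivityFactor(labels)
  if (nrow(x) != length(y)) stop("rows of x must match labels")
  y <- droplevels(y)
  if (nlevels(y) < 2L)
    stop("degenerate training set: fewer than 2 distinct labels")
  fit <- withr::with_seed(spec@seed, {
    if (spec@family == "svm_rbf") {
      e1071::svm(x, y, kernel = "radial", cost = spec@C, gamma = spec@gamma,
                 scale = FALSE)
    } else {
      ## decreasing path ending at the target lambda helps glmnet converge
      path <- sort(unique(c(10^seq(1, log10(max(spec@lambda, 1e-12)), length.out = 8),
                            spec@lambda)), decreasing = TRUE)
      glmnet::glmnet(x, y, family = "multinomial", alpha = 1,
                     lambda = path, standardize = FALSE)
    }
  })
  new("ActivityModel", spec = spec, fit = fit,
      classLevels = levels(y), nFeatures = ncol(x))
}

#' Predict activity labels
#'
#' @param model an [ActivityModel-class].
#' @param x feature matrix with the same columns as at training (already
#'   standardized with the training-fold normalizer).
#' @return Factor of predicted activities with levels [activityLevels()].
#' @export
predictActivities <- function(model, x) {
  x <- as.matrix(x)
  if (!nrow(x))
    return(factor(character(), levels = activityLevels()))
  if (ncol(x) != model@nFeatures)
    stop("feature count does not match the trained model")
  if (model@spec@family == "svm_rbf") {
    p <- as.character(predict(model@fit, x))
  } else {
    p <- as.character(predict(model@fit, newx = x, s = model@spec@lambda,
                              type = "class"))
  }
  factor(p, levels = activityLevels())
}

#' SMLR coefficient matrix at the fitted lambda
#'
#' @param model an [ActivityModel-class] with family `smlr`.
#' @return Numeric matrix of per-class feature coefficients (no intercepts),
#'   one column per class.
#' @export
smlrCoefficients <- function(model) {
  stopifnot(model@spec@family == "smlr")
  cf <- glmnet::coef.glmnet(model@fit, s = model@spec@lambda)
  do.call(cbind, lapply(cf, function(m) as.numeric(m)[-1L]))
}

#' Grid search over the study hyperparameter grid
#'
#' Hyperparameters are scanned over `{10^x : x integer, -5 <= x <= 5}` — the
#' full C x gamma product for the SVM (121 pairs), the lambda axis for SMLR
#' (11 values) — and scored by cross-validated accuracy under the supplied
#' folds. Ties are broken toward stronger regularization (smaller C, larger
#' lambda), then toward smaller gamma.
#'
#' @param family `"svm_rbf"` or `"smlr"`.
#' @param x feature matrix (unstandardized; per-fold normalizers are fitted
#'   on training rows only).
#' @param labels activity labels.
#' @param folds list of `list(train =, test =)` row-index pairs, e.g. from
#'   [tenfoldSplit()] applied to the clip metadata.
#' @param seed solver seed.
#' @return The accuracy-maximizing [ClassifierSpec-class].
#' @export
gridSearch <- function(family = c("svm_rbf", "smlr"), x, labels, folds,
                       seed = 20121107L) {
  family <- match.arg(family)
  x <- as.matrix(x)
  y <- asActivityFactor(labels)
  pow <- 10^(-5:5)
  grid <- if (family == "svm_rbf")
    expand.grid(C = pow, gamma = pow)
  else
    data.frame(lambda = pow)
  cvAccuracy <- function(spec) {
    hits <- 0L; total <- 0L
    for (f in folds) {
      nrm <- fitNormalizer(x[f$train, , drop = FALSE])
      m <- trainClassifier(spec, applyNormalizer(nrm, x[f$train, , drop = FALSE]),
                           y[f$train])
      p <- predictActivities(m, applyNormalizer(nrm, x[f$test, , drop = FALSE]))
      hits <- hits + sum(p == y[f$test])
      total <- total + length(f$test)
    }
    hits / total
  }
  accs <- vapply(seq_len(nrow(grid)), function(i) {
    spec <- if (family == "svm_rbf")
      ClassifierSpec(family, C = grid$C[i], gamma = grid$gamma[i], seed = seed)
    else
      ClassifierSpec(family, lambda = grid$lambda[i], seed = seed)
    cvAccuracy(spec)
  }, 0)
  ## ties -> stronger regularization (smaller C / larger lambda), smaller gamma
  ord <- if (family == "svm_rbf")
    order(-accs, grid$C, grid$gamma)
  else
    order(-accs, -grid$lambda)
  best <- ord[1L]
  if (family == "svm_rbf")
    ClassifierSpec(family, C = grid$C[best], gamma = grid$gamma[best],
                   seed = seed)
  else
    ClassifierSpec(family, lambda = grid$lambda[best], seed = seed)
}
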