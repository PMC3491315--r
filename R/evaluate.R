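#' Build a 5 x 5 confusion matrix
#'
#' Rows are the true activity, columns the prediction, classes in the fixed
#' order of [activityLevels()].
#'
#' @param true,predicted activity label vectors of equal length.
#' @return 5 x 5 integer matrix.
#' @export
confusionCounts <- function(true, predicted) {
  t <- asActivityFactor(true)
  p <- asActivityFactor(predicted)
  stopifnot(length(t) == length(p))
  m <- table(true = t, predicted = p)
  matrix(as.integer(m), 5L, 5L,
         dimnames = list(activityLevels(), activityLevels()))
}

#' Overall accuracy of a confusion matrix
#'
#' The sum of the correct classifications (the diagonal) divided by the sum
#' of all entries, in percent.
#'
#' @param confusion square non-negative count matrix with a positive grand
#'   total.
#' @param digits decimals for half-up rounding; `NULL` returns the exact
#'   value. Default 1, the precision used in reporting.
#' @return Accuracy in percent.
#' @export
accuracy <- function(confusion, digits = 1) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion))
    stop("confusion matrix must be square")
  total <- sum(confusion)
  if (total <= 0) stop("confusion matrix has no entries")
  acc <- 100 * sum(diag(confusion)) / total
  if (is.null(digits)) acc else roundHalfUp(acc, digits)
}

orderSourceClips <- function(meta) {
  first <- !duplicated(meta$sourceClipId)
  key <- meta[first, , drop = FALSE]
  key$sourceClipId[order(key$subjectId, key$sourceClipId, key$startSecond)]
}

#' Systematic 10-fold split at source-clip granularity
#'
#' Source clips are ordered deterministically (subject, session, window
#' position); fold k's test set is every 10th source clip starting at the
#' k-th. All orientation variants of a source clip travel together, so the
#' augmented near-copies of a test clip never sit in its training set. Set
#' `splitAugmentedIndependently = TRUE` to index augmented clips directly
#' instead — the leaky variant in which a clip's sign-flipped copies can
#' appear on the other side of a fold.
#'
#' @param meta data.frame of clip metadata (the `colData` of a
#'   [ClipFeatures-class] or [ClipSet-class]).
#' @param nFolds number of folds (default 10).
#' @param splitAugmentedIndependently ignore source-clip grouping.
#' @return List of `nFolds` elements `list(train =, test =)` of row indices;
#'   the test sets partition the rows.
#' @export
tenfoldSplit <- function(meta, nFolds = 10L,
                         splitAugmentedIndependently = FALSE) {
  meta <- as.data.frame(meta)
  if (splitAugmentedIndependently) {
    ord <- order(meta$subjectId, meta$sourceClipId, meta$startSecond,
                 meta$orientationVariant)
    grpOf <- integer(nrow(meta))
    grpOf[ord] <- seq_len(nrow(meta))
    nGroups <- nrow(meta)
  } else {
    sources <- orderSourceClips(meta)
    nGroups <- length(sources)
    grpOf <- match(meta$sourceClipId, sources)
  }
  if (nGroups < nFolds)
    stop("need at least ", nFolds, " source clips for ", nFolds, "-fold CV")
  lapply(seq_len(nFolds), function(k) {
    inTest <- (grpOf - k) %% nFolds == 0L
    list(train = which(!inTest), test = which(inTest))
  })
}

#' Leave-one-subject-out split
#'
#' One fold per subject: the test set is that subject's clips, the training
#' set everyone else's, so the score measures across-person generalization.
#'
#' @param meta data.frame of clip metadata.
#' @return List of per-subject `list(train =, test =, subject =)`.
#' @export
subjectwiseSplit <- function(meta) {
  meta <- as.data.frame(meta)
  subjects <- sort(unique(meta$subjectId))
  if (length(subjects) < 2L)
    stop("subject-wise CV needs at least 2 subjects")
  lapply(subjects, function(s)
    list(train = which(meta$subjectId != s),
         test = which(meta$subjectId == s), subject = s))
}

assertFoldPurity <- function(meta, folds, scheme) {
  key <- if (identical(scheme, "subjectwise")) meta$subjectId
         else meta$sourceClipId
  for (f in folds) {
    if (length(intersect(key[f$train], key[f$test])))
      stop("fold purity violated: a ",
           if (identical(scheme, "subjectwise")) "subject" else "source clip",
           " appears in both train and test")
  }
  invisible(TRUE)
}

#' Run one evaluation regime
#'
#' Three regimes reproduce the study designs: `tenfold` (systematic 10-fold
#' over ordered source clips — same subjects on both sides of each fold),
#' `subjectwise` (leave-one-subject-out) and `cross_population` (train on
#' every clip of one group, test on every clip of the other). Per fold, a
#' [FeatureNormalizer-class] is fitted on the training rows only, the
#' classifier trained, the test fold predicted, and one confusion matrix
#' accumulated over all folds.
#'
#' @param features a [ClipFeatures-class].
#' @param spec a [ClassifierSpec-class]; default = scheme default
#'   ([defaultSpec()]).
#' @param scheme `"tenfold"`, `"subjectwise"` or `"cross_population"`.
#' @param group for the within-population schemes, which group to evaluate
#'   (`NULL` = use all clips as given).
#' @param trainGroup,testGroup populations for `cross_population` (defaults:
#'   train healthy, test pd).
#' @param splitAugmentedIndependently see [tenfoldSplit()].
#' @return An [EvaluationResult-class].
#' @export
runEvaluation <- function(features,
                          spec = NULL,
                          scheme = c("tenfold", "subjectwise",
                                     "cross_population"),
                          group = NULL,
                          trainGroup = "healthy", testGroup = "pd",
                          splitAugmentedIndependently = FALSE) {
  scheme <- match.arg(scheme)
  stopifnot(is(features, "ClipFeatures"))
  if (is.null(spec)) spec <- defaultSpec("svm_rbf", scheme)
  meta <- as.data.frame(colData(features))
  x <- t(assay(features, "features"))
  if (scheme == "cross_population") {
    if (!all(c(trainGroup, testGroup) %in% meta$group))
      stop("cross_population needs clips from both groups")
    folds <- list(list(train = which(meta$group == trainGroup),
                       test = which(meta$group == testGroup)))
  } else {
    if (!is.null(group)) {
      keep <- meta$group == group
      meta <- meta[keep, , drop = FALSE]
      x <- x[keep, , drop = FALSE]
    }
    folds <- if (scheme == "tenfold")
      tenfoldSplit(meta, splitAugmentedIndependently =
                           splitAugmentedIndependently)
    else
      subjectwiseSplit(meta)
    assertFoldPurity(meta, folds,
                     if (scheme == "tenfold" && splitAugmentedIndependently)
                       "clipwise" else scheme)
  }
  y <- asActivityFactor(meta$activity)
  conf <- matrix(0L, 5L, 5L,
                 dimnames = list(activityLevels(), activityLevels()))
  foldRows <- lapply(seq_along(folds), function(k) {
    f <- folds[[k]]
    nrm <- fitNormalizer(x[f$train, , drop = FALSE])
    model <- trainClassifier(spec,
                             applyNormalizer(nrm, x[f$train, , drop = FALSE]),
                             y[f$train])
    pred <- predictActivities(model,
                              applyNormalizer(nrm, x[f$test, , drop = FALSE]))
    cf <- confusionCounts(y[f$test], pred)
    conf <<- conf + cf
    data.frame(fold = k, nTrain = length(f$train), nTest = length(f$test),
               accuracy = accuracy(cf, digits = NULL))
  })
  new("EvaluationResult", scheme = scheme, spec = spec, confusion = conf,
      accuracyPercent = accuracy(conf, digits = NULL),
      folds = do.call(rbind, foldRows))
}

#' Write an EvaluationResult as JSON
#'
#' @param result an [EvaluationResult-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEvaluationResult <- function(result, path) {
  spec <- result@spec
  out <- list(
    scheme = result@scheme,
    classifier = list(family = spec@family, C = spec@C, gamma = spec@gamma,
                      lambda = spec@lambda, seed = spec@seed),
    classOrder = activityLevels(),
    confusion = unname(apply(result@confusion, 1L, as.integer,
                             simplify = FALSE)),
    accuracyPercent = roundHalfUp(result@accuracyPercent, 1),
    folds = result@folds)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
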