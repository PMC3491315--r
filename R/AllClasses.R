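#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData colData<-
NULL

#' SensorRecording: one labeled accelerometer bout
#'
#' One subject performing one labeled activity; timestamped triaxial samples
#' in units of g at a possibly variable sampling rate.
#'
#' @slot subjectId opaque subject identifier.
#' @slot group `"healthy"` or `"pd"`.
#' @slot activity one of [activityLevels()].
#' @slot sessionId opaque bout identifier (one recording = one bout).
#' @slot time numeric vector of timestamps in seconds, strictly increasing.
#' @slot accel numeric matrix, one row per sample, columns `x`, `y`, `z` (g).
#'
#' @export
setClass("SensorRecording",
  representation(
    subjectId = "character",
    group = "character",
    activity = "character",
    sessionId = "character",
    time = "numeric",
    accel = "matrix"
  )
)

setValidity("SensorRecording", function(object) {
  msg <- character()
  if (!object@group %in% groupLevels())
    msg <- c(msg, "group must be 'healthy' or 'pd'")
  if (!object@activity %in% activityLevels())
    msg <- c(msg, "unknown activity label")
  n <- length(object@time)
  if (!is.numeric(object@accel) || ncol(object@accel) != 3L)
    msg <- c(msg, "accel must be a numeric matrix with 3 columns (x, y, z)")
  else if (nrow(object@accel) != n)
    msg <- c(msg, "accel must have one row per timestamp")
  if (n >= 2L && any(diff(object@time) <= 0))
    msg <- c(msg, "timestamps must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Construct a SensorRecording
#'
#' @param subjectId,group,activity,sessionId recording metadata.
#' @param time numeric timestamps (seconds), strictly increasing.
#' @param accel n x 3 numeric matrix of accelerations in g (columns x, y, z).
#' @return A [SensorRecording-class] object.
#' @export
SensorRecording <- function(subjectId, group, activity, time, accel,
                            sessionId = "s1") {
  accel <- as.matrix(accel)
  colnames(accel) <- c("x", "y", "z")
  new("SensorRecording",
    subjectId = as.character(subjectId), group = as.character(group),
    activity = as.character(activity), sessionId = as.character(sessionId),
    time = as.numeric(time), accel = accel)
}

setMethod("show", "SensorRecording", function(object) {
  n <- length(object@time)
  span <- if (n) diff(range(object@time)) else 0
  cat(sprintf(
    "SensorRecording: subject %s (%s), activity '%s', %d samples over %.1f s\n",
    object@subjectId, object@group, object@activity, n, span))
})

#' ClipSet: fixed-length clips of uniform-rate triaxial data
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding 10 s,
#' 20 Hz clips. The single assay `"accel"` is a 600 x n matrix: rows are the
#' flattened clip values `x000..x199, y000..y199, z000..z199`; each column is
#' one clip. Column metadata carries `clipId`, `sourceClipId`, `subjectId`,
#' `group`, `activity`, `orientationVariant` and `startSecond`.
#'
#' @export
setClass("ClipSet", contains = "SummarizedExperiment")

.clipMetaCols <- c("clipId", "sourceClipId", "subjectId", "group",
                   "activity", "orientationVariant", "startSecond")

setValidity("ClipSet", function(object) {
  msg <- character()
  if (!"accel" %in% SummarizedExperiment::assayNames(object))
    return("assay 'accel' missing")
  if (nrow(object) != 600L)
    msg <- c(msg, "assay must have 600 rows (200 samples x 3 axes)")
  missing <- setdiff(.clipMetaCols, colnames(colData(object)))
  if (length(missing))
    msg <- c(msg, paste("missing colData columns:",
                        paste(missing, collapse = ", ")))
  else {
    ov <- colData(object)$orientationVariant
    if (length(ov) && !all(ov %in% 0:3))
      msg <- c(msg, "orientationVariant must be in 0..3")
    if (length(object) && anyDuplicated(colData(object)$clipId))
      msg <- c(msg, "clipId values must be unique")
  }
  if (length(msg)) msg else TRUE
})

clipRowNames <- function(nPerAxis = 200L) {
  as.vector(vapply(c("x", "y", "z"), function(a)
    sprintf("%s%03d", a, seq_len(nPerAxis) - 1L), character(nPerAxis)))
}

#' Construct a ClipSet from clip matrices
#'
#' @param clips list of 200 x 3 numeric matrices (columns x, y, z).
#' @param meta data.frame with one row per clip and columns `clipId`,
#'   `sourceClipId`, `subjectId`, `group`, `activity`, `orientationVariant`,
#'   `startSecond`.
#' @return A [ClipSet-class].
#' @export
ClipSet <- function(clips, meta) {
  stopifnot(length(clips) == nrow(meta))
  mat <- vapply(clips, function(m) {
    m <- as.matrix(m)
    if (!identical(dim(m), c(200L, 3L)))
      stop("each clip must be a 200 x 3 matrix")
    as.vector(m)
  }, numeric(600L))
  mat <- matrix(mat, nrow = 600L,
                dimnames = list(clipRowNames(), meta$clipId))
  new("ClipSet", SummarizedExperiment(
    assays = list(accel = mat), colData = DataFrame(meta)))
}

setMethod("show", "ClipSet", function(object) {
  cd <- colData(object)
  cat(sprintf("ClipSet: %d clips (%d source windows), %d subject(s)\n",
              ncol(object),
              length(unique(cd$sourceClipId)),
              length(unique(cd$subjectId))))
  if (ncol(object)) {
    tab <- table(factor(cd$activity, levels = activityLevels()))
    cat("  activities:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  }
})

#' ClipFeatures: per-clip feature vectors
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass whose single assay
#' `"features"` is a 178 x n matrix (rows named by [featureNames()], one
#' column per clip) with the same column metadata as the [ClipSet-class] it
#' was computed from.
#'
#' @export
setClass("ClipFeatures", contains = "SummarizedExperiment")

setValidity("ClipFeatures", function(object) {
  msg <- character()
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    return("assay 'features' missing")
  if (nrow(object) != 178L)
    msg <- c(msg, "feature vector must have length 178")
  if (!identical(rownames(object), featureNames()))
    msg <- c(msg, "rownames must equal featureNames()")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ClipFeatures", function(object) {
  cat(sprintf("ClipFeatures: 178 features x %d clips, %d subject(s)\n",
              ncol(object), length(unique(colData(object)$subjectId))))
})

#' FeatureNormalizer: per-feature standardization fitted on training data
#'
#' @slot center,scale numeric vectors (length = number of features);
#'   zero-variance features get scale 1 so they map to 0.
#' @export
setClass("FeatureNormalizer",
  representation(center = "numeric", scale = "numeric"))

setMethod("show", "FeatureNormalizer", function(object) {
  cat(sprintf("FeatureNormalizer over %d features\n", length(object@center)))
})

#' ClassifierSpec: classifier family and hyperparameters
#'
#' Defaults follow the study setup: SMLR penalty lambda = 1e-4; SVM
#' `C = 1, gamma = 0.1` for subject-wise and cross-population runs and
#' `C = 10, gamma = 1` for systematic 10-fold runs (see [defaultSpec()]).
#'
#' @slot family `"svm_rbf"` or `"smlr"`.
#' @slot C,gamma RBF-SVM soft margin and kernel width (svm_rbf only).
#' @slot lambda L1 penalty coefficient (smlr only).
#' @slot seed integer seed for any stochastic solver component.
#' @export
setClass("ClassifierSpec",
  representation(family = "character", C = "numeric", gamma = "numeric",
                 lambda = "numeric", seed = "integer"),
  prototype(family = "svm_rbf", C = 1, gamma = 0.1, lambda = 1e-4,
            seed = 20121107L))

setValidity("ClassifierSpec", function(object) {
  msg <- character()
  if (!object@family %in% c("svm_rbf", "smlr"))
    msg <- c(msg, "family must be 'svm_rbf' or 'smlr'")
  if (object@C <= 0 || object@gamma <= 0)
    msg <- c(msg, "C and gamma must be positive")
  if (object@lambda < 0) msg <- c(msg, "lambda must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a ClassifierSpec
#'
#' @param family `"svm_rbf"` or `"smlr"`.
#' @param C,gamma SVM soft-margin cost and RBF width.
#' @param lambda SMLR L1 penalty.
#' @param seed solver seed.
#' @return A [ClassifierSpec-class].
#' @export
ClassifierSpec <- function(family = c("svm_rbf", "smlr"), C = 1, gamma = 0.1,
                           lambda = 1e-4, seed = 20121107L) {
  family <- match.arg(family)
  ## slots assigned individually: an argument named C would otherwise
  ## partially match new()'s Class formal
  obj <- new("ClassifierSpec")
  obj@family <- family
  obj@C <- as.numeric(C)
  obj@gamma <- as.numeric(gamma)
  obj@lambda <- as.numeric(lambda)
  obj@seed <- as.integer(seed)
  validObject(obj)
  obj
}

#' Study-default hyperparameters per evaluation scheme
#'
#' @param family classifier family.
#' @param scheme `"tenfold"`, `"subjectwise"` or `"cross_population"`.
#' @return A [ClassifierSpec-class] with the scheme's default settings:
#'   `C = 10, gamma = 1` for 10-fold, `C = 1, gamma = 0.1` otherwise;
#'   `lambda = 1e-4` for SMLR in all schemes.
#' @export
defaultSpec <- function(family = c("svm_rbf", "smlr"),
                        scheme = c("tenfold", "subjectwise",
                                   "cross_population")) {
  family <- match.arg(family)
  scheme <- match.arg(scheme)
  if (identical(scheme, "tenfold"))
    ClassifierSpec(family, C = 10, gamma = 1)
  else
    ClassifierSpec(family, C = 1, gamma = 0.1)
}

setMethod("show", "ClassifierSpec", function(object) {
  if (object@family == "svm_rbf")
    cat(sprintf("ClassifierSpec: RBF-SVM (C = %g, gamma = %g)\n",
                object@C, object@gamma))
  else
    cat(sprintf("ClassifierSpec: SMLR (lambda = %g)\n", object@lambda))
})

#' ActivityModel: a fitted classifier
#'
#' @slot spec the [ClassifierSpec-class] used.
#' @slot fit underlying fitted object (e1071 svm or glmnet).
#' @slot classLevels activity labels seen at training.
#' @slot nFeatures number of features at training.
#' @export
setClass("ActivityModel",
  representation(spec = "ClassifierSpec", fit = "ANY",
                 classLevels = "character", nFeatures = "integer"))

setMethod("show", "ActivityModel", function(object) {
  cat(sprintf("ActivityModel (%s) over %d features, %d classes\n",
              object@spec@family, object@nFeatures,
              length(object@classLevels)))
})

#' EvaluationResult: one evaluation run
#'
#' @slot scheme `"tenfold"`, `"subjectwise"` or `"cross_population"`.
#' @slot spec the [ClassifierSpec-class] used.
#' @slot confusion 5 x 5 integer matrix, rows = true activity, columns =
#'   predicted, class order [activityLevels()].
#' @slot accuracyPercent overall accuracy in percent.
#' @slot folds data.frame of per-fold sizes and accuracies.
#' @export
setClass("EvaluationResult",
  representation(scheme = "character", spec = "ClassifierSpec",
                 confusion = "matrix", accuracyPercent = "numeric",
                 folds = "data.frame"))

setMethod("show", "EvaluationResult", function(object) {
  cat(sprintf("EvaluationResult [%s]: accuracy %.1f%% over %d clips\n",
              object@scheme, object@accuracyPercent, sum(object@confusion)))
})

#' SubjectProfile: generative parameters for one synthetic subject
#'
#' All numeric slots are in the units of the signal model: amplitudes in g,
#' frequencies in Hz, angles in radians.
#'
#' @slot subjectId,group identity.
#' @slot pocketOrientation discrete orientation variant 0..3.
#' @slot tiltAngle,tiltAxis small random pocket tilt (<= 15 degrees).
#' @slot gaitFrequency,gaitAmplitude,gaitCycleJitter gait model parameters;
#'   jitter is the coefficient of variation of the stride period.
#' @slot tremorAmplitude,tremorFrequency rest-tremor oscillation (pd only).
#' @slot dyskinesiaAmplitude,dyskinesiaFrequency low-frequency involuntary
#'   movement (pd only).
#' @slot sensorNoiseSd white-noise standard deviation in g.
#' @slot postureOffset per-subject posture-angle random effect (radians).
#' @slot seed subject-level RNG seed.
#' @export
setClass("SubjectProfile",
  representation(
    subjectId = "character", group = "character",
    pocketOrientation = "integer",
    tiltAngle = "numeric", tiltAxis = "numeric",
    gaitFrequency = "numeric", gaitAmplitude = "numeric",
    gaitCycleJitter = "numeric",
    tremorAmplitude = "numeric", tremorFrequency = "numeric",
    dyskinesiaAmplitude = "numeric", dyskinesiaFrequency = "numeric",
    sensorNoiseSd = "numeric", postureOffset = "numeric",
    seed = "integer"))

setValidity("SubjectProfile", function(object) {
  msg <- character()
  if (!object@group %in% groupLevels())
    msg <- c(msg, "group must be 'healthy' or 'pd'")
  amps <- c(object@gaitAmplitude, object@tremorAmplitude,
            object@dyskinesiaAmplitude, object@sensorNoiseSd)
  if (any(amps < 0)) msg <- c(msg, "amplitudes must be non-negative")
  if (!object@pocketOrientation %in% 0:3)
    msg <- c(msg, "pocketOrientation must be in 0..3")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SubjectProfile", function(object) {
  cat(sprintf(
    "SubjectProfile %s (%s): gait %.2f Hz (amp %.2f g, jitter %.2f), tremor %.2f g, dyskinesia %.2f g\n",
    object@subjectId, object@group, object@gaitFrequency,
    object@gaitAmplitude, object@gaitCycleJitter, object@tremorAmplitude,
    object@dyskinesiaAmplitude))
})
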