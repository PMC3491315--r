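#' Names of the 178 clip features
#'
#' The feature vector is organized in 11 named blocks: per-axis mean and
#' |mean| (6); population standard deviation, skewness and excess kurtosis
#' (9); the same four statistics of the first-differenced signal, the "jerk"
#' (12); RMS (3); RMS of the boxcar-smoothed signal, 5- and 10-point kernels
#' (6); min, max and the min/max of the absolute signal (12); 9-bin z-score
#' histogram counts per axis over [-4, 4] (27); magnitudes of DFT bins 0-31
#' per axis (96); mean Euclidean norm of the acceleration vector (1); mean
#' per-sample cross products xy, xz, yz (3); and mean absolute per-sample
#' cross products (3). Within a block, axes are ordered x, y, z.
#'
#' @return Character vector of 178 unique feature names, in extraction order.
#' @export
featureNames <- function() {
  ax <- c("x", "y", "z")
  pairs <- c("xy", "xz", "yz")
  c(paste0("mean_", ax), paste0("absmean_", ax),
    paste0("sd_", ax), paste0("skew_", ax), paste0("kurt_", ax),
    paste0("jerk_mean_", ax), paste0("jerk_sd_", ax),
    paste0("jerk_skew_", ax), paste0("jerk_kurt_", ax),
    paste0("rms_", ax),
    paste0("rms_smooth5_", ax), paste0("rms_smooth10_", ax),
    paste0("min_", ax), paste0("max_", ax),
    paste0("absmin_", ax), paste0("absmax_", ax),
    as.vector(t(outer(ax, 1:9, function(a, b)
      sprintf("hist_%s_bin%d", a, b)))),
    as.vector(t(outer(ax, 0:31, function(a, b)
      sprintf("fourier_%s_%02d", a, b)))),
    "overall_mean_accel",
    paste0("crossprod_", pairs),
    paste0("abs_crossprod_", pairs))
}

## Population (biased) central moments; skewness and excess kurtosis are 0
## by convention for a zero-variance signal so no NaN is ever emitted.
momentStats <- function(v) {
  m <- mean(v)
  d <- v - m
  m2 <- mean(d^2)
  if (m2 == 0)
    return(c(mean = m, sd = 0, skew = 0, kurt = 0))
  c(mean = m, sd = sqrt(m2),
    skew = mean(d^3) / m2^1.5,
    kurt = mean(d^4) / m2^2 - 3)
}

## Centered boxcar moving average with symmetric (reflected-edge) padding;
## for an even kernel the window extends one further point to the right.
boxcarSmooth <- function(v, k) {
  n <- length(v)
  left <- (k - 1L) %/% 2L
  right <- k - 1L - left
  padded <- c(v[left:1], v, v[n:(n - right + 1L)])
  as.numeric(stats::filter(padded, rep(1 / k, k), sides = 1)[k:(k + n - 1L)])
}

zscoreHistogram <- function(v, bins = 9L, lim = 4) {
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  z <- if (s == 0) rep(0, length(v)) else (v - m) / s
  idx <- floor((z + lim) / (2 * lim / bins)) + 1L
  idx <- pmin(pmax(idx, 1L), bins)
  tabulate(idx, nbins = bins)
}

#' Compute the 178-value feature vector of one clip
#'
#' @param clip a 200 x 3 numeric matrix (columns x, y, z, in g) or a
#'   [ClipSet-class] (one feature vector per clip).
#' @return For a matrix, a named numeric vector of length 178 (names from
#'   [featureNames()]); for a ClipSet, a [ClipFeatures-class].
#' @export
setGeneric("extractFeatures", function(clip) standardGeneric("extractFeatures"))

#' @rdname extractFeatures
#' @export
setMethod("extractFeatures", "matrix", function(clip) {
  if (!identical(dim(clip), c(200L, 3L)))
    stop("clip must be a 200 x 3 matrix")
  if (anyNA(clip) || any(!is.finite(clip)))
    stop("malformed clip: non-finite values")
  axes <- lapply(1:3, function(j) clip[, j])
  mom <- vapply(axes, momentStats, numeric(4L))
  jerk <- vapply(axes, function(v) momentStats(diff(v)), numeric(4L))
  rms <- vapply(axes, function(v) sqrt(mean(v^2)), 0)
  sm5 <- vapply(axes, function(v) sqrt(mean(boxcarSmooth(v, 5L)^2)), 0)
  sm10 <- vapply(axes, function(v) sqrt(mean(boxcarSmooth(v, 10L)^2)), 0)
  mins <- vapply(axes, min, 0)
  maxs <- vapply(axes, max, 0)
  absmin <- vapply(axes, function(v) min(abs(v)), 0)
  absmax <- vapply(axes, function(v) max(abs(v)), 0)
  hist <- unlist(lapply(axes, zscoreHistogram))
  four <- unlist(lapply(axes, function(v) Mod(stats::fft(v))[1:32]))
  norm <- sqrt(rowSums(clip^2))
  cp <- c(mean(clip[, 1] * clip[, 2]), mean(clip[, 1] * clip[, 3]),
          mean(clip[, 2] * clip[, 3]))
  acp <- c(mean(abs(clip[, 1] * clip[, 2])), mean(abs(clip[, 1] * clip[, 3])),
           mean(abs(clip[, 2] * clip[, 3])))
  out <- c(mom["mean", ], abs(mom["mean", ]),
           mom["sd", ], mom["skew", ], mom["kurt", ],
           jerk["mean", ], jerk["sd", ], jerk["skew", ], jerk["kurt", ],
           rms, sm5, sm10,
           mins, maxs, absmin, absmax,
           hist, four, mean(norm), cp, acp)
  names(out) <- featureNames()
  out
})

#' @rdname extractFeatures
#' @export
setMethod("extractFeatures", "ClipSet", function(clip) {
  mat <- assay(clip, "accel")
  feats <- vapply(seq_len(ncol(mat)), function(i)
    extractFeatures(matrix(mat[, i], ncol = 3L,
                           dimnames = list(NULL, c("x", "y", "z")))),
    numeric(178L))
  feats <- matrix(feats, nrow = 178L,
                  dimnames = list(featureNames(), colnames(mat)))
  new("ClipFeatures", SummarizedExperiment(
    assays = list(features = feats), colData = colData(clip)))
})

#' Read/write the per-clip feature table CSV
#'
#' One row per clip: metadata columns `clipId, sourceClipId, subjectId,
#' group, activity, orientationVariant, startSecond` followed by the 178
#' feature columns named by [featureNames()].
#'
#' @param features a [ClipFeatures-class].
#' @param path CSV path.
#' @return `writeFeatureTable` returns `path` invisibly; `readFeatureTable`
#'   a [ClipFeatures-class].
#' @export
writeFeatureTable <- function(features, path) {
  meta <- as.data.frame(colData(features))
  vals <- t(assay(features, "features"))
  data.table::fwrite(cbind(meta, as.data.frame(vals)), path)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  dt <- as.data.frame(data.table::fread(path, colClasses = list(
    character = c("clipId", "sourceClipId", "subjectId", "group",
                  "activity"))))
  meta <- dt[, .clipMetaCols, drop = FALSE]
  mat <- t(as.matrix(dt[, featureNames(), drop = FALSE]))
  rownames(mat) <- featureNames()
  colnames(mat) <- meta$clipId
  new("ClipFeatures", SummarizedExperiment(
    assays = list(features = mat), colData = DataFrame(meta)))
}
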