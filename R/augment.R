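#' The four pocket-orientation sign transforms
#'
#' An elongated phone sits in a front pocket in four discrete ways (screen
#' in/out crossed with right-side up/upside down). In accelerometer
#' coordinates the orientations differ only by axis signs: flipping right
#' side up to upside down negates x and y; turning the screen inward negates
#' x and z; composing the two negates y and z. Together with the identity
#' these four sign patterns form a Klein four-group of 180-degree rotations
#' about the device axes.
#'
#' @return 4 x 3 numeric matrix of axis signs; row k is orientation variant
#'   k-1, columns x, y, z.
#' @export
orientationTransforms <- function() {
  matrix(c( 1,  1,  1,
           -1, -1,  1,
           -1,  1, -1,
            1, -1, -1),
         nrow = 4L, byrow = TRUE,
         dimnames = list(paste0("variant", 0:3), c("x", "y", "z")))
}

#' Apply one orientation transform to a clip matrix
#'
#' @param mat 200 x 3 clip matrix.
#' @param variant orientation variant in 0..3.
#' @return The sign-flipped clip matrix.
#' @export
applyOrientation <- function(mat, variant) {
  stopifnot(variant %in% 0:3)
  sweep(mat, 2L, orientationTransforms()[variant + 1L, ], `*`)
}

#' Generate the four orientation variants of each clip
#'
#' Every unaugmented clip yields itself plus three sign-flipped copies, one
#' per non-identity orientation transform. Variants share the clip's
#' `sourceClipId`, label, subject and group, so downstream fold splits can
#' keep them together; `orientationVariant` is set to 0..3.
#'
#' @param clipset a [ClipSet-class] with all `orientationVariant == 0`.
#' @return A [ClipSet-class] with `4 * ncol(clipset)` clips, source clips
#'   kept adjacent.
#' @export
augmentClips <- function(clipset) {
  stopifnot(is(clipset, "ClipSet"))
  cd <- colData(clipset)
  if (length(clipset) && any(cd$orientationVariant != 0L))
    stop("clips are already orientation-augmented (variant != 0)")
  if (!ncol(clipset))
    return(clipset)
  signs <- orientationTransforms()
  mat <- assay(clipset, "accel")
  blocks <- lapply(0:3, function(v) {
    s <- rep(signs[v + 1L, ], each = 200L)
    mat * s
  })
  n <- ncol(clipset)
  ord <- as.vector(vapply(seq_len(n), function(i) i + n * (0:3),
                          integer(4L)))
  big <- do.call(cbind, blocks)[, ord, drop = FALSE]
  meta <- as.data.frame(cd)[rep(seq_len(n), each = 4L), , drop = FALSE]
  meta$orientationVariant <- rep(0:3, n)
  meta$clipId <- sprintf("%s.o%d", meta$sourceClipId, meta$orientationVariant)
  rownames(meta) <- NULL
  colnames(big) <- meta$clipId
  new("ClipSet", SummarizedExperiment(
    assays = list(accel = big), colData = DataFrame(meta)))
}
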