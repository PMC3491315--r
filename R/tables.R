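#' Read a confusion matrix from CSV
#'
#' The dialect is a header row of class names preceded by an `activity`
#' column of row names, classes in the order of [activityLevels()].
#'
#' @param path CSV path.
#' @return 5 x 5 integer matrix, rows = true activity, columns = predicted.
#' @export
readConfusionCsv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!identical(df[[1L]], activityLevels()) ||
      !identical(colnames(df)[-1L], activityLevels()))
    stop("confusion CSV classes must match activityLevels() order")
  m <- as.matrix(df[, -1L])
  rownames(m) <- activityLevels()
  storage.mode(m) <- "integer"
  if (any(m < 0)) stop("confusion counts must be non-negative")
  m
}

#' The five published classification matrices
#'
#' Confusion matrices bundled with the package, transcribed from the
#' original study report: 10-fold CV on healthy subjects (table 2) and on
#' parkinsonian patients (3), patients classified with a healthy-trained
#' model (4), and subject-wise CV for healthy subjects (5) and patients (6).
#' Entries count 10 s clips (orientation-augmented, so multiples of 4).
#'
#' @param table integer 2..6.
#' @return 5 x 5 integer confusion matrix.
#' @export
publishedConfusion <- function(table) {
  stopifnot(table %in% 2:6)
  path <- system.file("extdata", sprintf("table%d.csv", table),
                      package = "PocketActivity", mustWork = TRUE)
  readConfusionCsv(path)
}

#' Recompute the five headline accuracies from the published matrices
#'
#' @return data.frame with one row per published matrix: evaluation scheme,
#'   population, clip count and overall accuracy (percent, one decimal).
#' @export
reproduceTables <- function() {
  info <- data.frame(
    table = 2:6,
    scheme = c("tenfold", "tenfold", "cross_population",
               "subjectwise", "subjectwise"),
    population = c("healthy", "pd", "pd (healthy-trained)",
                   "healthy", "pd"),
    stringsAsFactors = FALSE)
  mats <- lapply(info$table, publishedConfusion)
  info$nClips <- vapply(mats, sum, 0L)
  info$accuracyPercent <- vapply(mats, accuracy, 0)
  info
}
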