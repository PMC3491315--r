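#' Activity class labels in canonical order
#'
#' The fixed class order used everywhere in the package: confusion-matrix
#' rows/columns, classifier label levels and reporting.
#'
#' @return Character vector of the five activity labels.
#' @export
activityLevels <- function() {
  c("walking", "standing", "holding", "sitting", "not_wearing")
}

#' Cohort group labels
#' @return Character vector `c("healthy", "pd")`.
#' @export
groupLevels <- function() c("healthy", "pd")

## Half-up rounding to `digits` decimals (base round() is banker's).
roundHalfUp <- function(x, digits = 1) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}

asActivityFactor <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), activityLevels())
  if (length(bad))
    stop("unknown activity label(s): ", paste(bad, collapse = ", "))
  factor(x, levels = activityLevels())
}

## Derive a stream of child seeds from a master seed, kept below 2^31.
deriveSeeds <- function(seed, n) {
  (as.integer(seed) + 7919L * seq_len(n)) %% .Machine$integer.max
}
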