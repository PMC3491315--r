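#' Read raw recordings from CSV
#'
#' The raw dialect has one row per accelerometer sample with columns
#' `subject_id,group,session_id,activity,t,x,y,z` (t in seconds, x/y/z in g)
#' and a mandatory header. Each (subject, session) pair is one labeled bout
#' and becomes one [SensorRecording-class].
#'
#' @param path CSV file path.
#' @return List of [SensorRecording-class] objects, ordered by subject then
#'   session then first timestamp.
#' @export
readRecordings <- function(path) {
  req <- c("subject_id", "group", "session_id", "activity", "t", "x", "y", "z")
  dt <- data.table::fread(path, colClasses = list(
    character = c("subject_id", "group", "session_id", "activity")))
  missing <- setdiff(req, names(dt))
  if (length(missing))
    stop("raw CSV missing column(s): ", paste(missing, collapse = ", "))
  keys <- unique(dt[, c("subject_id", "session_id")])
  recs <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- dt[dt$subject_id == keys$subject_id[i] &
              dt$session_id == keys$session_id[i], ]
    act <- unique(sub$activity)
    if (length(act) != 1L)
      stop("session ", keys$session_id[i], " mixes activity labels")
    SensorRecording(keys$subject_id[i], unique(sub$group)[1L], act,
                    sub$t, cbind(x = sub$x, y = sub$y, z = sub$z),
                    sessionId = keys$session_id[i])
  })
  ord <- order(vapply(recs, function(r) r@subjectId, ""),
               vapply(recs, function(r) r@sessionId, ""),
               vapply(recs, function(r) r@time[1L], 0))
  recs[ord]
}

#' Write recordings to the raw CSV dialect
#'
#' @param recordings list of [SensorRecording-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeRecordings <- function(recordings, path) {
  tabs <- lapply(recordings, function(r)
    data.table::data.table(
      subject_id = r@subjectId, group = r@group, session_id = r@sessionId,
      activity = r@activity, t = r@time,
      x = r@accel[, 1L], y = r@accel[, 2L], z = r@accel[, 3L]))
  data.table::fwrite(data.table::rbindlist(tabs), path)
  invisible(path)
}

#' Resample a recording to a uniform rate by linear interpolation
#'
#' Phone accelerometers log at a variable rate (roughly 15-25 Hz depending
#' on movement); downstream clips require a uniform 20 Hz grid. The grid is
#' anchored at the first timestamp and never extends beyond the last one
#' (no extrapolation).
#'
#' @param recording a [SensorRecording-class] with at least 2 samples.
#' @param targetHz target sampling rate in Hz (default 20).
#' @return A [SensorRecording-class] on the uniform grid.
#' @export
resampleToUniform <- function(recording, targetHz = 20) {
  stopifnot(is(recording, "SensorRecording"), targetHz > 0)
  t <- recording@time
  if (length(t) < 2L)
    stop("cannot resample a recording with fewer than 2 samples")
  if (any(diff(t) <= 0))
    stop("malformed recording: timestamps not strictly increasing")
  grid <- seq(t[1L], t[length(t)], by = 1 / targetHz)
  accel <- vapply(1:3, function(j)
    stats::approx(t, recording@accel[, j], xout = grid)$y,
    numeric(length(grid)))
  SensorRecording(recording@subjectId, recording@group, recording@activity,
                  grid, accel, sessionId = recording@sessionId)
}

#' Segment a uniform-rate recording into fixed-length clips
#'
#' Consecutive non-overlapping windows of `clipSeconds` at `rateHz`. With
#' `trimEnds = TRUE` (the default) the first and last window of the bout are
#' discarded, allowing time for the phone to enter and leave the pocket. A
#' trailing partial window is always dropped. Recordings too short to yield
#' any window return an empty ClipSet, with a message.
#'
#' @param recording a [SensorRecording-class] already uniform at `rateHz`
#'   (see [resampleToUniform()]).
#' @param clipSeconds clip duration in seconds (default 10).
#' @param trimEnds discard the first and last window of the bout.
#' @param rateHz expected uniform rate (default 20).
#' @return A [ClipSet-class]; all clips have `orientationVariant = 0`.
#' @export
segmentClips <- function(recording, clipSeconds = 10, trimEnds = TRUE,
                         rateHz = 20) {
  stopifnot(is(recording, "SensorRecording"))
  dt <- diff(recording@time)
  if (length(dt) && max(abs(dt - 1 / rateHz)) > 1e-6)
    stop("recording is not uniform at ", rateHz,
         " Hz; run resampleToUniform() first")
  w <- as.integer(round(clipSeconds * rateHz))
  n <- nrow(recording@accel)
  nWin <- n %/% w
  idx <- seq_len(nWin)
  if (trimEnds && nWin >= 1L) idx <- idx[-c(1L, length(idx))]
  if (!length(idx) || nWin < 1L) {
    message("recording ", recording@sessionId, " too short (",
            nWin, " window(s)); no clips emitted")
    idx <- integer()
  }
  clips <- lapply(idx, function(k)
    recording@accel[((k - 1L) * w + 1L):(k * w), , drop = FALSE])
  ids <- sprintf("%s.%s.w%02d", recording@subjectId, recording@sessionId,
                 if (length(idx)) idx else integer())
  meta <- data.frame(
    clipId = ids, sourceClipId = ids,
    subjectId = rep(recording@subjectId, length(idx)),
    group = rep(recording@group, length(idx)),
    activity = rep(recording@activity, length(idx)),
    orientationVariant = rep(0L, length(idx)),
    startSecond = (idx - 1L) * clipSeconds,
    stringsAsFactors = FALSE)
  ClipSet(clips, meta)
}

#' Segment many recordings and pool the clips
#'
#' @param recordings list of uniform-rate [SensorRecording-class] objects.
#' @param ... passed to [segmentClips()].
#' @return A single pooled [ClipSet-class].
#' @export
segmentRecordings <- function(recordings, ...) {
  sets <- lapply(recordings, segmentClips, ...)
  do.call(bindClipSets, sets)
}

bindClipSets <- function(...) {
  sets <- list(...)
  sets <- sets[vapply(sets, ncol, 0L) > 0L]
  if (!length(sets)) return(ClipSet(list(), emptyClipMeta()))
  mats <- do.call(cbind, lapply(sets, function(s) assay(s, "accel")))
  meta <- do.call(rbind, lapply(sets, function(s)
    as.data.frame(colData(s))))
  rownames(meta) <- NULL
  new("ClipSet", SummarizedExperiment(
    assays = list(accel = mats), colData = DataFrame(meta)))
}

emptyClipMeta <- function() {
  data.frame(clipId = character(), sourceClipId = character(),
             subjectId = character(), group = character(),
             activity = character(), orientationVariant = integer(),
             startSecond = numeric(), stringsAsFactors = FALSE)
}

#' Extract one clip as a 200 x 3 matrix
#'
#' @param clipset a [ClipSet-class].
#' @param i column index or clipId.
#' @return 200 x 3 numeric matrix with columns x, y, z.
#' @export
clipMatrix <- function(clipset, i) {
  v <- assay(clipset, "accel")[, i]
  matrix(v, ncol = 3L, dimnames = list(NULL, c("x", "y", "z")))
}

#' Read/write the clip store CSV
#'
#' One row per clip: metadata columns then 600 value columns
#' `x000..x199, y000..y199, z000..z199`.
#'
#' @param clipset a [ClipSet-class].
#' @param path CSV path.
#' @return `writeClipSet` returns `path` invisibly; `readClipSet` a
#'   [ClipSet-class].
#' @export
writeClipSet <- function(clipset, path) {
  meta <- as.data.frame(colData(clipset))
  vals <- t(assay(clipset, "accel"))
  data.table::fwrite(cbind(meta, as.data.frame(vals)), path)
  invisible(path)
}

#' @rdname writeClipSet
#' @export
readClipSet <- function(path) {
  dt <- as.data.frame(data.table::fread(path, colClasses = list(
    character = c("clipId", "sourceClipId", "subjectId", "group",
                  "activity"))))
  valCols <- clipRowNames()
  meta <- dt[, .clipMetaCols, drop = FALSE]
  mat <- t(as.matrix(dt[, valCols, drop = FALSE]))
  rownames(mat) <- valCols
  colnames(mat) <- meta$clipId
  new("ClipSet", SummarizedExperiment(
    assays = list(accel = mat), colData = DataFrame(meta)))
}
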