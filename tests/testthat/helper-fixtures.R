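# Shared in-code fixtures for the test suite.

# a deterministic pseudo-random clip (200 x 3, values in a plausible g range)
randomClip <- function(seed = 1, scale = 0.5) {
  withr::with_seed(seed, {
    matrix(stats::rnorm(600, sd = scale), 200, 3,
           dimnames = list(NULL, c("x", "y", "z")))
  })
}

# uniform 20 Hz recording of given duration with arbitrary smooth content
uniformRecording <- function(duration = 60, subjectId = "S1", group = "healthy",
                             activity = "walking", sessionId = "b01") {
  t <- seq(0, duration, by = 0.05)
  accel <- cbind(x = 0.3 * sin(2 * pi * 2 * t),
                 y = 1 + 0.4 * sin(2 * pi * 2 * t + 1),
                 z = 0.1 * cos(2 * pi * 1 * t))
  SensorRecording(subjectId, group, activity, t, accel, sessionId = sessionId)
}

# tiny ClipSet: nClips source clips across subjects/activities
tinyClipSet <- function(nClips = 10, nSubjects = 2, seed = 7) {
  acts <- rep_len(activityLevels(), nClips)
  subs <- rep_len(sprintf("S%d", seq_len(nSubjects)), nClips)
  clips <- lapply(seq_len(nClips), function(i) randomClip(seed + i))
  meta <- data.frame(
    clipId = sprintf("c%02d", seq_len(nClips)),
    sourceClipId = sprintf("c%02d", seq_len(nClips)),
    subjectId = subs, group = "healthy", activity = acts,
    orientationVariant = 0L,
    startSecond = 10 * (seq_len(nClips) - 1),
    stringsAsFactors = FALSE)
  ClipSet(clips, meta)
}

# two well-separated gaussian blobs labeled with two activity names
blobData <- function(n = 50, gap = 8, seed = 11) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n * 2), n, 2),
               matrix(rnorm(n * 2, mean = gap), n, 2))
    list(x = x, y = rep(c("walking", "sitting"), each = n))
  })
}

# small synthetic feature set shared by classify/evaluate tests (cached)
.smallFeatures <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- studyFeatures(generativeConfig(
        nHealthy = 3, nPD = 2, boutSeconds = 30, seed = 99))
    cache
  }
})
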