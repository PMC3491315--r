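test_that("accuracy is trace over grand total, in percent", {
  m <- diag(c(10, 20, 30, 5, 5))
  dimnames(m) <- list(activityLevels(), activityLevels())
  expect_equal(accuracy(m), 100)
  m2 <- m; m2[1, 2] <- 30  # 70 correct of 100
  expect_equal(accuracy(m2), 70)
  # invariant under simultaneous row/column permutation
  p <- c(3, 1, 5, 2, 4)
  expect_equal(accuracy(m2[p, p]), accuracy(m2))
  expect_error(accuracy(matrix(0, 5, 5)), "no entries")
  expect_error(accuracy(matrix(1, 2, 3)), "square")
  # half-up rounding at one decimal: 1641/2184 = 75.137 -> 75.1
  expect_equal(accuracy(diag(c(1641, 0, 0, 0, 0)) + (2184 - 1641) *
                          outer(c(0, 1, 0, 0, 0), c(1, 0, 0, 0, 0))), 75.1)
})

test_that("confusionCounts tabulates in the fixed class order", {
  true <- c("walking", "walking", "sitting", "not_wearing")
  pred <- c("walking", "standing", "sitting", "sitting")
  cm <- confusionCounts(true, pred)
  expect_equal(rownames(cm), activityLevels())
  expect_equal(cm["walking", "walking"], 1L)
  expect_equal(cm["walking", "standing"], 1L)
  expect_equal(cm["not_wearing", "sitting"], 1L)
  expect_equal(sum(cm), 4L)
})

test_that("tenfold split keeps orientation variants together and partitions the data", {
  aug <- augmentClips(tinyClipSet(10))
  meta <- as.data.frame(SummarizedExperiment::colData(aug))
  folds <- tenfoldSplit(meta)
  expect_length(folds, 10L)
  # 40 augmented clips from 10 sources: each fold tests 1 source x 4 variants
  expect_true(all(vapply(folds, function(f) length(f$test), 0L) == 4L))
  allTest <- sort(unlist(lapply(folds, `[[`, "test")))
  expect_equal(allTest, seq_len(40L))  # union = everything, disjoint
  for (f in folds) {
    expect_length(intersect(meta$sourceClipId[f$train],
                            meta$sourceClipId[f$test]), 0L)
    expect_equal(sort(c(f$train, f$test)), seq_len(40L))
  }
  expect_error(tenfoldSplit(meta[meta$sourceClipId %in%
                                   unique(meta$sourceClipId)[1:5], ]),
               "at least 10")
})

test_that("the augmented-independent compatibility split leaks variants across folds", {
  aug <- augmentClips(tinyClipSet(10))
  meta <- as.data.frame(SummarizedExperiment::colData(aug))
  folds <- tenfoldSplit(meta, splitAugmentedIndependently = TRUE)
  leaked <- any(vapply(folds, function(f)
    length(intersect(meta$sourceClipId[f$train],
                     meta$sourceClipId[f$test])) > 0, TRUE))
  expect_true(leaked)
})

test_that("subject-wise split leaves exactly one subject out per fold", {
  meta <- data.frame(subjectId = rep(sprintf("S%02d", 1:18), each = 4),
                     sourceClipId = sprintf("c%03d", 1:72))
  folds <- subjectwiseSplit(meta)
  expect_length(folds, 18L)
  for (f in folds) {
    expect_length(intersect(meta$subjectId[f$train],
                            meta$subjectId[f$test]), 0L)
    expect_equal(sort(c(f$train, f$test)), seq_len(72L))
  }
  # two subjects -> two complementary folds
  two <- subjectwiseSplit(data.frame(subjectId = c("A", "A", "B"),
                                     sourceClipId = c("1", "2", "3")))
  expect_length(two, 2L)
  expect_equal(two[[1]]$test, two[[2]]$train)
  expect_error(subjectwiseSplit(data.frame(subjectId = "A",
                                           sourceClipId = "1")),
               "at least 2")
})

test_that("runEvaluation conserves counts and is reproducible", {
  fs <- .smallFeatures()
  res <- runEvaluation(fs, syntheticStudySpec(), "subjectwise",
                       group = "healthy")
  nHealthy <- sum(SummarizedExperiment::colData(fs)$group == "healthy")
  expect_equal(sum(res@confusion), nHealthy)
  expect_equal(res@accuracyPercent, accuracy(res@confusion, digits = NULL))
  expect_equal(sum(res@folds$nTest), nHealthy)
  # identical inputs -> identical result
  res2 <- runEvaluation(fs, syntheticStudySpec(), "subjectwise",
                        group = "healthy")
  expect_identical(res@confusion, res2@confusion)
  expect_identical(res@folds, res2@folds)
})

test_that("cross-population trains on one group and tests every clip of the other", {
  fs <- .smallFeatures()
  res <- runEvaluation(fs, syntheticStudySpec(), "cross_population")
  cd <- SummarizedExperiment::colData(fs)
  expect_equal(sum(res@confusion), sum(cd$group == "pd"))
  expect_equal(nrow(res@folds), 1L)
  # reversed direction evaluates the healthy clips
  rev <- runEvaluation(fs, syntheticStudySpec(), "cross_population",
                       trainGroup = "pd", testGroup = "healthy")
  expect_equal(sum(rev@confusion), sum(cd$group == "healthy"))
  healthyOnly <- fs[, cd$group == "healthy"]
  expect_error(runEvaluation(healthyOnly, syntheticStudySpec(),
                             "cross_population"), "both groups")
})

test_that("evaluation results serialize to JSON", {
  fs <- .smallFeatures()
  res <- runEvaluation(fs, syntheticStudySpec(), "cross_population")
  f <- withr::local_tempfile(fileext = ".json")
  writeEvaluationResult(res, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$scheme, "cross_population")
  expect_equal(back$accuracyPercent, accuracy(res@confusion))
  expect_equal(sum(unlist(back$confusion)), sum(res@confusion))
})

test_that("published matrices load with verified totals and accuracies", {
  tab <- reproduceTables()
  expect_equal(tab$table, 2:6)
  expect_equal(tab$nClips, c(3388L, 2184L, 2184L, 3388L, 2184L))
  m <- publishedConfusion(5)
  expect_equal(dim(m), c(5L, 5L))
  expect_equal(rownames(m), activityLevels())
  expect_true(all(m >= 0))
})
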