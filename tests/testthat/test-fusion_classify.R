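test_that("fusion concatenates in order and lengths add exactly", {
  expect_equal(fuseFeatures(c(1, 2), c(3)), c(1, 2, 3), ignore_attr = TRUE)
  set.seed(1)
  for (i in 1:10) {
    a <- rnorm(sample(1:50, 1)); b <- rnorm(sample(1:50, 1))
    f <- fuseFeatures(a, b)
    expect_length(f, length(a) + length(b))
    expect_equal(as.numeric(f), c(a, b))
  }
  f1 <- FeatureSet(matrix(1:4, 2), "hog", c("s1", "s2"), c("x", "y"))
  f2 <- FeatureSet(matrix(5:8, 2), "deep", c("s1", "s2"), c("x", "y"))
  fu <- fuseFeatures(f1, f2)
  expect_identical(featureTag(fu), "fused")
  expect_identical(dim(featureValues(fu)), c(4L, 2L))
  expect_equal(featureValues(fu)[, "s1"], c(1, 2, 5, 6), ignore_attr = TRUE)
  # pairing guard: mismatched source ids
  f3 <- FeatureSet(matrix(5:8, 2), "deep", c("s1", "s3"), c("x", "y"))
  expect_error(fuseFeatures(f1, f3), "source ids differ")
  a <- c(1, 2); attr(a, "sourceId") <- "u"
  b <- c(3); attr(b, "sourceId") <- "v"
  expect_error(fuseFeatures(a, b), "different sources")
})

test_that("one-vs-rest SVM separates Gaussian blobs and respects contracts", {
  set.seed(42)
  n <- 25
  x <- rbind(matrix(rnorm(2 * n), n),        # class a at origin
             matrix(rnorm(2 * n, 8), n),     # class b far away
             cbind(rnorm(n, 8), rnorm(n, -8)),
             cbind(rnorm(n, -8), rnorm(n, 8)))
  y <- rep(c("a", "b", "c", "d"), each = n)
  clf <- fitClassifier(x, y, SVMConfig(), seed = 1)
  expect_length(clf@machines, 4L)           # one binary machine per class
  expect_identical(clf@classOrder, c("a", "b", "c", "d"))
  expect_identical(predictLabels(clf, x), y)  # 100% training accuracy
  expect_identical(predictLabels(clf, x[0, , drop = FALSE]), character(0))
  # closed world: predictions on arbitrary points stay in the label set
  z <- matrix(rnorm(40, 0, 20), 20)
  expect_true(all(predictLabels(clf, z) %in% clf@classOrder))
  expect_error(fitClassifier(x[1:n, ], y[1:n], SVMConfig(), 1),
               "at least 2 classes")
  expect_error(predictLabels(clf, matrix(0, 2, 3)), "does not match")
  expect_error(fitClassifier(cbind(x[, 1], NA), y, SVMConfig(), 1),
               "non-finite")
})

test_that("coordinate order of fused blocks does not change accuracy", {
  imgs <- separableFixture(n = 8, seed = 33, side = 64)
  lbp <- lbpFeatures(imgs, LBPConfig(), side = 64)
  hog <- hogFeatures(imgs, HOGConfig(cellPx = 16), side = 64)
  labs <- featureLabels(lbp)
  ab <- fuseFeatures(lbp, hog)
  ba <- fuseFeatures(hog, lbp)
  idx <- seq_along(imgs) %% 4 != 0
  accOf <- function(fs) {
    clf <- fitClassifier(fs[, idx], config = SVMConfig(), seed = 2)
    mean(predictLabels(clf, fs[, !idx]) == labs[!idx])
  }
  expect_equal(accOf(ab), accOf(ba))
})

test_that("persisted classifiers carry provenance metadata", {
  set.seed(3)
  x <- rbind(matrix(rnorm(20), 10), matrix(rnorm(20, 5), 10))
  clf <- fitClassifier(x, rep(c("a", "b"), each = 10), SVMConfig(), 1)
  f <- tempfile(fileext = ".rds")
  writeClassifier(clf, f)
  meta <- jsonlite::read_json(paste0(f, ".json"), simplifyVector = TRUE)
  expect_identical(meta$decomposition, "one-vs-rest")
  expect_identical(meta$featureDim, 2L)
  back <- readClassifier(f, expectDim = 2)
  expect_identical(predictLabels(back, x), predictLabels(clf, x))
  expect_error(readClassifier(f, expectTag = "hog"), "trained on")
  expect_error(readClassifier(f, expectDim = 99), "dimension")
})
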