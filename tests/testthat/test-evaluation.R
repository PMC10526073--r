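test_that("confusion matrices count true-vs-predicted pairs", {
  cm <- confusionMatrix(c("A", "A", "B"), c("A", "B", "B"), c("A", "B"))
  expect_equal(unname(cm@counts), rbind(c(1L, 1L), c(0L, 1L)))
  # perfect predictions -> diagonal
  y <- rep(c("A", "B", "C"), 4)
  d <- confusionMatrix(y, y, c("A", "B", "C"))
  expect_true(all(d@counts[upper.tri(d@counts) | lower.tri(d@counts)] == 0))
  expect_equal(diag(d@counts), c(A = 4L, B = 4L, C = 4L))
  # empty inputs -> all-zero K x K
  e <- confusionMatrix(character(0), character(0), c("A", "B"))
  expect_true(all(e@counts == 0))
  expect_error(confusionMatrix("A", c("A", "B"), c("A", "B")), "length")
  expect_error(confusionMatrix("Z", "A", c("A", "B")), "outside")
  # row sums = per-class true counts (conservation)
  set.seed(5)
  yt <- sample(c("A", "B", "C"), 60, replace = TRUE)
  yp <- sample(c("A", "B", "C"), 60, replace = TRUE)
  cm2 <- confusionMatrix(yt, yp, c("A", "B", "C"))
  expect_equal(rowSums(cm2@counts), table(factor(yt, c("A", "B", "C"))),
               ignore_attr = TRUE)
})

test_that("metrics reproduce hand-computed values and the diagonal identity", {
  # binary counts TP=50 FN=10 FP=5 TN=35 for class A
  cm <- new("ConfusionMatrix", counts = rbind(c(50L, 10L), c(5L, 35L)),
            classOrder = c("A", "B"))
  m <- classMetrics(cm)
  expect_equal(m@perClass$precision[1], 50 / 55)
  expect_equal(m@perClass$recall[1], 50 / 60)
  p <- 50 / 55; r <- 50 / 60
  expect_equal(m@perClass$f1[1], 2 * p * r / (p + r))
  expect_equal(m@aggregate[["accuracy"]], 0.85)
  # one-vs-rest accuracy of class A: (TP + TN) / total
  expect_equal(m@perClass$accuracy[1], m@perClass$recall[1])
  # perfect diagonal scores 1 everywhere
  d <- classMetrics(new("ConfusionMatrix",
                        counts = diag(c(3L, 7L, 2L)),
                        classOrder = c("A", "B", "C")))
  expect_true(all(unlist(d@perClass[, -1]) == 1))
  expect_true(all(d@aggregate == 1))
  expect_error(classMetrics(new("ConfusionMatrix",
                                counts = matrix(0L, 2, 2),
                                classOrder = c("A", "B"))), "empty")
})

test_that("zero-denominator cases warn and report 0", {
  cm <- new("ConfusionMatrix",
            counts = rbind(c(5L, 0L, 0L), c(0L, 5L, 0L), c(0L, 0L, 0L)),
            classOrder = c("A", "B", "C"))
  expect_warning(expect_warning(m <- classMetrics(cm), "precision"),
                 "recall")
  expect_equal(m@perClass$precision[3], 0)
  expect_equal(m@perClass$recall[3], 0)
  expect_equal(m@perClass$f1[3], 0)
})

test_that("macro recall equals overall accuracy for balanced classes", {
  set.seed(7)
  for (i in 1:5) {
    k <- sample(2:5, 1)
    n <- 40
    yt <- rep(LETTERS[1:k], each = n)
    yp <- sample(LETTERS[1:k], k * n, replace = TRUE)
    m <- classMetrics(confusionMatrix(yt, yp, LETTERS[1:k]))
    expect_equal(m@aggregate[["recall"]], m@aggregate[["accuracy"]],
                 tolerance = 1e-12)
  }
})

test_that("metrics are invariant to class permutation", {
  set.seed(9)
  yt <- sample(c("A", "B", "C"), 90, replace = TRUE)
  yp <- sample(c("A", "B", "C"), 90, replace = TRUE)
  m1 <- classMetrics(confusionMatrix(yt, yp, c("A", "B", "C")))
  m2 <- classMetrics(confusionMatrix(yt, yp, c("C", "A", "B")))
  expect_equal(m1@aggregate, m2@aggregate)
  p1 <- m1@perClass[order(m1@perClass$class), ]
  p2 <- m2@perClass[order(m2@perClass$class), ]
  expect_equal(p1, p2, ignore_attr = TRUE)
})

test_that("reports serialize with a per-class block and an ALL row", {
  cm <- confusionMatrix(rep(c("A", "B"), c(6, 6)),
                        rep(c("A", "B", "B", "A"), c(5, 1, 4, 2)),
                        c("A", "B"))
  f <- tempfile(fileext = ".csv")
  writeMetricsCSV(classMetrics(cm), f)
  df <- read.csv(f)
  expect_identical(df$class, c("ALL", "A", "B"))
  expect_equal(df$accuracy[1], 0.75)
  g <- tempfile(fileext = ".csv")
  writeConfusionCSV(cm, g)
  expect_equal(read.csv(g)$A, c(5L, 2L))
})
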