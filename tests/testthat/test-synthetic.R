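test_that("the generator produces balanced, bounded, deterministic images", {
  cfg <- SynthConfig(nPerClass = 5, imageSide = 64,
                     views = c("upper", "lower"), seed = 17)
  imgs <- generateBeakDataset(cfg)
  expect_length(imgs, 5 * 4 * 2)
  labs <- vapply(imgs, function(x) x@label, "")
  expect_true(all(table(labs) == 10))
  views <- vapply(imgs, function(x) x@view, "")
  expect_true(all(table(labs, views) == 5))
  expect_true(all(vapply(imgs, function(x)
    min(x@pixels) >= 0 && max(x@pixels) <= 255, TRUE)))
  expect_false(anyDuplicated(vapply(imgs, function(x) x@sourceId, "")) > 0)
  # bitwise determinism
  imgs2 <- generateBeakDataset(cfg)
  expect_identical(lapply(imgs, function(x) x@pixels),
                   lapply(imgs2, function(x) x@pixels))
  # a different seed changes the pixels
  imgs3 <- generateBeakDataset(SynthConfig(nPerClass = 5, imageSide = 64,
                                           views = c("upper", "lower"),
                                           seed = 18))
  expect_false(identical(imgs[[1]]@pixels, imgs3[[1]]@pixels))
})

test_that("ground truth rows are distinct iff the separations are positive", {
  gt <- describeGroundTruth(SynthConfig())
  expect_identical(nrow(gt), 4L)
  expect_identical(anyDuplicated(gt[, -1]), 0L)
  gt0 <- describeGroundTruth(SynthConfig(shapeSeparation = 0,
                                         textureSeparation = 0))
  expect_identical(nrow(unique(gt0[, -1])), 1L)
  # stripe periods ordered consistently with the texture separation scaling
  expect_true(all(diff(gt$stripePeriod) > 0))
  gtLow <- describeGroundTruth(SynthConfig(textureSeparation = 0.3))
  expect_true(all(gt$stripePeriod[-1] >= gtLow$stripePeriod[-1]))
  # shape-only separation leaves texture parameters identical
  gtS <- describeGroundTruth(SynthConfig(shapeSeparation = 0.8,
                                         textureSeparation = 0))
  expect_identical(nrow(unique(gtS[, c("stripePeriod", "stripeContrast")])),
                   1L)
  expect_identical(anyDuplicated(gtS[, c("hoodCrestRatio", "curvature")]), 0L)
})

test_that("zero separation collapses the class-conditional distributions", {
  cfg0 <- SynthConfig(nPerClass = 2, imageSide = 64, views = "upper",
                      shapeSeparation = 0, textureSeparation = 0, seed = 9)
  imgs <- generateBeakDataset(cfg0)
  # images of different classes at matching within-class index are drawn
  # from the same distribution; their summary statistics agree closely
  m <- vapply(imgs, function(x) mean(x@pixels), 0)
  byClass <- tapply(m, vapply(imgs, function(x) x@label, ""), mean)
  expect_lt(diff(range(byClass)), 5)
})

test_that("views differ by reflection plus a hood/crest shift", {
  cfg <- SynthConfig(nPerClass = 1, imageSide = 64, noiseSd = 0, seed = 30)
  imgs <- generateBeakDataset(cfg)
  up <- imgs[[1]]@pixels
  lo <- imgs[[2]]@pixels
  expect_false(identical(up, lo))
  # both views contain a dark silhouette on the light board
  expect_gt(mean(up == 255 | up > 240), 0.4)
  expect_gt(mean(up < 150), 0.1)
  expect_gt(mean(lo < 150), 0.1)
})
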