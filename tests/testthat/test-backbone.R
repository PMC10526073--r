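test_that("profiles expose their declared feature dimensions deterministically", {
  cfg <- BackboneConfig("deskSmall", inputSide = 32L, nClasses = 4L,
                        pooledDim = 24L, seed = 5L)
  bb <- buildBackbone(cfg)
  expect_identical(bb@featureDim, 24L)
  imgs <- separableFixture(n = 2, side = 48)[1:5]
  fs <- extractDeep(bb, imgs)
  expect_identical(dim(featureValues(fs)), c(24L, 5L))
  expect_identical(featureTag(fs), "deep")
  expect_true(all(is.finite(featureValues(fs))))
  # same seed -> identical weights -> identical features
  bb2 <- buildBackbone(cfg)
  expect_identical(featureValues(extractDeep(bb2, imgs)), featureValues(fs))
  # different seed -> different weights
  bb3 <- buildBackbone(BackboneConfig("deskSmall", inputSide = 32L,
                                      nClasses = 4L, pooledDim = 24L,
                                      seed = 6L))
  expect_false(identical(featureValues(extractDeep(bb3, imgs)),
                         featureValues(fs)))
  expect_error(BackboneConfig("deskSmall", epochs = 0L), "epochs")
  expect_error(new("BackboneConfig", profile = "vgg",
                   inputSide = 224L, nClasses = 4L, pooledDim = 64L,
                   epochs = 1L, batchSize = 1L,
                   lrSchedule = rbind(c(1, 1, 1e-3)), momentum = 0.9,
                   seed = 1L), "unknown profile")
})

test_that("features are invariant to batch composition in eval mode", {
  imgs <- separableFixture(n = 4, side = 48)[c(1, 5, 9, 13)]
  bb <- buildBackbone(BackboneConfig("deskSmall", inputSide = 32L,
                                     nClasses = 4L, pooledDim = 16L,
                                     batchSize = 4L, seed = 2L))
  together <- featureValues(extractDeep(bb, imgs))
  alone <- sapply(imgs, function(im) featureValues(extractDeep(bb, list(im))))
  expect_equal(together, alone, tolerance = 1e-5, ignore_attr = TRUE)
  # duplicated input -> identical feature vector
  dup <- featureValues(extractDeep(bb, imgs[c(1, 1)]))
  expect_identical(dup[, 1], dup[, 2])
})

test_that("the learning-rate schedule switches at the configured epochs", {
  sched <- rbind(c(1, 50, 1e-3), c(51, 100, 1e-4))
  expect_equal(BeakFusion:::lrAtEpoch(sched, 50), 1e-3)
  expect_equal(BeakFusion:::lrAtEpoch(sched, 51), 1e-4)
  expect_equal(BeakFusion:::lrAtEpoch(sched, 100), 1e-4)
  expect_error(BackboneConfig("deskSmall",
                              lrSchedule = rbind(c(1, 10, 0))), "rate")
})

test_that("training reduces validation loss and recovers separable classes", {
  imgs <- separableFixture(n = 32, seed = 21, side = 96)
  sp <- splitDataset(imgs, 0.2, 0.25, seed = 1)
  ids <- vapply(imgs, function(x) x@sourceId, "")
  cfg <- BackboneConfig("deskSmall", inputSide = 48L, nClasses = 4L,
                        pooledDim = 64L, epochs = 16L, batchSize = 8L,
                        lrSchedule = deskLrSchedule(16L), seed = 2L)
  bb <- trainBackbone(buildBackbone(cfg), imgs[ids %in% sp@train],
                      imgs[ids %in% sp@val], seed = 1L)
  h <- bb@history
  expect_identical(nrow(h), 16L)
  expect_lt(h$valLoss[16], h$valLoss[1])
  expect_identical(h$lr[1], 0.02)
  # parameter-recovery: high-separation classes learned within 20 epochs
  expect_gte(max(h$valAcc), 0.9)
  expect_true(bb@trained)
  expect_identical(bb@classOrder, sort(unique(vapply(imgs, function(x)
    x@label, ""))))
  expect_error(trainBackbone(buildBackbone(cfg), list(), list(), seed = 1),
               "empty")
  expect_error(trainBackbone(buildBackbone(cfg), imgs[1:20], imgs[1:5],
                             seed = 1), "overlap")
})
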