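test_that("identity, involution and exact-permutation affine maps are exact", {
  m <- randomGray(9, seed = 2)
  expect_equal(applyAffine(m, diag(2), c(0, 0)), m, tolerance = 1e-12)
  flip <- diag(c(-1, 1))
  expect_equal(applyAffine(applyAffine(m, flip), flip), m,
               tolerance = 1e-12)
  expect_equal(applyAffine(m, flip), m[, ncol(m):1], tolerance = 1e-12)
  # quarter rotation of an asymmetric 3x3 grid = index permutation
  a <- matrix(1:9 * 10, 3, 3)
  rot <- matrix(c(0, 1, -1, 0), 2, 2)  # 90 degrees counterclockwise on (x,y)
  got <- applyAffine(a, rot)
  perm <- t(a)[, 3:1]  # transpose then reverse columns rotates the grid
  expect_equal(got, perm, tolerance = 1e-12)
  expect_error(applyAffine(a, matrix(0, 2, 2)), "singular")
})

test_that("integer translation equals an array shift with background fill", {
  m <- randomGray(7, seed = 5)
  got <- applyAffine(m, diag(2), b = c(2, 0))  # shift 2 px right
  want <- matrix(255, 7, 7)
  want[, 3:7] <- m[, 1:5]
  expect_equal(got, want, tolerance = 1e-12)
  got2 <- applyAffine(m, diag(2), b = c(0, -3))  # shift 3 px up
  want2 <- matrix(255, 7, 7)
  want2[1:4, ] <- m[4:7, ]
  expect_equal(got2, want2, tolerance = 1e-12)
})

test_that("sampled augmentations preserve labels, count and determinism", {
  img <- BeakImage(randomGray(16, seed = 3), "E_luminosa", "lower", "img7")
  expect_identical(sampleAugmentations(img, AugmentSpec(nPerImage = 0L)),
                   list())
  spec <- AugmentSpec(nPerImage = 4L, seed = 11L)
  aug <- sampleAugmentations(img, spec)
  expect_length(aug, 4L)
  for (a in aug) {
    expect_identical(a@label, "E_luminosa")
    expect_identical(a@view, "lower")
    expect_identical(dim(a@pixels), dim(img@pixels))
    expect_true(all(a@pixels >= 0 & a@pixels <= 255))
  }
  expect_identical(vapply(aug, function(x) x@sourceId, ""),
                   paste0("img7_aug", 1:4))
  aug2 <- sampleAugmentations(img, spec)
  expect_identical(lapply(aug, function(x) x@pixels),
                   lapply(aug2, function(x) x@pixels))
  # different seed, different images
  aug3 <- sampleAugmentations(img, AugmentSpec(nPerImage = 4L, seed = 12L))
  expect_false(identical(aug[[1]]@pixels, aug3[[1]]@pixels))
})

test_that("augment specs reject invalid parameter ranges", {
  expect_error(AugmentSpec(pFlip = 1.2), "pFlip")
  expect_error(AugmentSpec(cropFracRange = c(0.5, 1.2)), "cropFracRange")
  expect_error(AugmentSpec(nPerImage = -1L), "nPerImage")
})
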