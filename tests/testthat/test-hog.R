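test_that("gradients follow central differences with edge replication", {
  side <- 8
  expect_true(all(gradients(matrix(5, side, side))$magnitude == 0))
  ramp <- matrix(rep(seq_len(side), each = side), side)  # I(x, y) = x
  g <- gradients(ramp)
  inner <- 2:(side - 1)
  expect_true(all(g$magnitude[inner, inner] == 2))
  expect_true(all(g$angle[inner, inner] == 0))
  # transposition swaps the gradient roles
  r <- randomGray(12, seed = 8)
  gr <- gradients(r); gt <- gradients(t(r))
  expect_equal(gt$magnitude, t(gr$magnitude), tolerance = 1e-12)
  expect_error(gradients(matrix(1, 2, 2)), "3 x 3")
})

test_that("cell histograms vote with linear bin interpolation", {
  cfg <- HOGConfig(cellPx = 4L)
  z <- matrix(0, 8, 8)
  expect_true(all(cellHistograms(z, z, cfg) == 0))
  # one pixel exactly at the center of bin 3 (angle 50 deg): all mass there
  mag <- z; ang <- z
  mag[2, 2] <- 7; ang[2, 2] <- 50
  h <- cellHistograms(mag, ang, cfg)
  expect_equal(h[1, 1, ], c(0, 0, 7, rep(0, 6)))
  # halfway between centers 10 and 30: split evenly
  ang[2, 2] <- 20
  h2 <- cellHistograms(mag, ang, cfg)
  expect_equal(h2[1, 1, 1:2], c(3.5, 3.5))
  expect_error(cellHistograms(matrix(0, 9, 9), matrix(0, 9, 9), cfg),
               "not divisible")
})

test_that("descriptor length follows the block geometry formula", {
  img <- randomGray(256, seed = 2)
  expect_length(hogDescriptor(img, HOGConfig(cellPx = 16)), 8100)
  expect_length(hogDescriptor(img, HOGConfig(cellPx = 32)), 1764)
  expect_length(hogDescriptor(img, HOGConfig(cellPx = 64)), 324)
  expect_identical(hogLength(256, HOGConfig(cellPx = 64)), 324L)
  # constant image -> zero vector through the epsilon guard
  expect_true(all(hogDescriptor(matrix(9, 64, 64),
                                HOGConfig(cellPx = 16)) == 0))
  expect_error(hogDescriptor(randomGray(32), HOGConfig(cellPx = 32)),
               "fewer cells")
})

test_that("blocks are L2-normalized and the descriptor is contrast invariant", {
  img <- randomGray(64, seed = 12)
  cfg <- HOGConfig(cellPx = 16)
  d <- hogDescriptor(img, cfg)
  blockLen <- cfg@blockCells^2 * cfg@nBins
  for (k in seq_len(length(d) / blockLen) - 1L) {
    nrm <- sqrt(sum(d[k * blockLen + seq_len(blockLen)]^2))
    expect_lte(nrm, 1 + 1e-12)
    expect_gte(nrm, 0.9)  # eps is small relative to these block energies
  }
  expect_equal(hogDescriptor(img * 0.5, cfg), d, tolerance = 2e-2,
               ignore_attr = TRUE)
})

test_that("vectorized descriptor equals the literal per-pixel translation", {
  for (seed in 1:3) {
    img <- randomGray(32, seed = 100 + seed)
    expect_equal(hogDescriptor(img, HOGConfig(cellPx = 8)),
                 oracleHOG(img, C = 8), tolerance = 1e-9, ignore_attr = TRUE)
  }
  img <- randomGray(64, seed = 200)
  expect_equal(hogDescriptor(img, HOGConfig(cellPx = 16)),
               oracleHOG(img, C = 16), tolerance = 1e-9, ignore_attr = TRUE)
})
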