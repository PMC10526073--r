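test_that("sampling positions follow the circular geometry with y down", {
  cfg <- LBPConfig(R = 1, P = 8)
  pos <- samplePositions(c(10, 10), cfg)
  expect_equal(dim(pos), c(8L, 2L))
  expect_equal(unname(pos[1, ]), c(11, 10), tolerance = 1e-12)   # p = 0
  expect_equal(unname(pos[3, ]), c(10, 9), tolerance = 1e-12)    # p = 2, y up
  cfg2 <- LBPConfig(R = 2, P = 16)
  pos2 <- samplePositions(c(10, 10), cfg2)
  p <- 3
  expect_equal(unname(pos2[p + 1, ]),
               c(10 + 2 * cos(2 * pi * p / 16), 10 - 2 * sin(2 * pi * p / 16)),
               tolerance = 1e-12)
})

test_that("codes threshold interpolated neighbors with S(0) = 1", {
  cfg <- LBPConfig()
  expect_equal(lbpCode(matrix(7, 5, 5), c(3, 3), cfg), 255)  # constant
  m <- matrix(5, 3, 3); m[2, 2] <- 4
  expect_equal(lbpCode(m, c(2, 2), cfg), 255)  # all samples >= 4.9 > 4
  # shift invariance of individual codes
  r <- randomGray(9, seed = 4)
  for (ctr in list(c(3, 3), c(5, 6))) {
    expect_identical(lbpCode(r, ctr, cfg), lbpCode(r + 30, ctr, cfg))
  }
})

test_that("uniform mapping has P(P-1)+3 bins, verified by enumeration", {
  # independent enumeration of circular transitions over all 256 codes
  transitions <- function(code, P) {
    bits <- as.integer(intToBits(code))[1:P]
    sum(bits != c(bits[-1], bits[1]))
  }
  nUnif <- sum(vapply(0:255, transitions, 0L, P = 8L) <= 2)
  expect_identical(nUnif, 58L)
  expect_identical(lbpNBins(LBPConfig()), 59L)
  bins <- uniformBin(0:255, 8)
  expect_identical(length(unique(bins)), 59L)
  expect_identical(max(bins), 59L)                       # catch-all present
  expect_identical(sum(bins == 59L), 256L - 58L)
  b0 <- uniformBin(0, 8); b255 <- uniformBin(255, 8)
  expect_true(b0 != b255 && b0 < 59 && b255 < 59)  # dedicated uniform bins
  expect_error(uniformBin(256, 8), "out of")
})

test_that("descriptor length, normalization and shift invariance hold across configs", {
  img <- randomGray(40, seed = 6)
  for (cfg in list(LBPConfig(1, 8, 1), LBPConfig(2, 8, 2),
                   LBPConfig(2, 12, 1), LBPConfig(1.5, 10, 3))) {
    d <- lbpDescriptor(img, cfg)
    expect_length(d, cfg@gridN^2 * (cfg@P * (cfg@P - 1) + 3))
    nb <- lbpNBins(cfg)
    for (cell in seq_len(cfg@gridN^2) - 1L)
      expect_equal(sum(d[cell * nb + seq_len(nb)]), 1, tolerance = 1e-9)
  }
  d1 <- lbpDescriptor(img, LBPConfig())
  d2 <- lbpDescriptor(img + 25, LBPConfig())
  expect_equal(d1, d2, tolerance = 0)
  # constant image: all mass in the all-ones uniform bin
  dc <- lbpDescriptor(matrix(100, 64, 64), LBPConfig())
  expect_equal(dc[uniformBin(255, 8)], 1)
  expect_equal(sum(dc), 1)
  expect_error(lbpDescriptor(matrix(1, 2, 2), LBPConfig()), "smaller")
})

test_that("vectorized descriptor equals the literal per-pixel translation", {
  for (seed in 1:3) {
    img <- randomGray(32, seed = seed)
    expect_equal(lbpDescriptor(img, LBPConfig(R = 1, P = 8)),
                 oracleLBP(img, 1, 8), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
  img <- randomGray(24, seed = 9)
  expect_equal(lbpDescriptor(img, LBPConfig(R = 2, P = 16)),
               oracleLBP(img, 2, 16), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(lbpDescriptor(img, LBPConfig(R = 1.5, P = 8, gridN = 2)),
               oracleLBP(img, 1.5, 8, 2), tolerance = 1e-9,
               ignore_attr = TRUE)
})
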