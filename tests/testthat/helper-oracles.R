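# Independent, deliberately naive reference implementations used to check
# the package's vectorized descriptor paths. Everything here is scalar
# loops written directly from the defining formulas.

# Bilinear interpolation of m at a single (x, y) point, 1-based coords.
oracleBilinearAt <- function(m, x, y) {
  x0 <- max(1L, min(floor(x), ncol(m) - 1L))
  y0 <- max(1L, min(floor(y), nrow(m) - 1L))
  fx <- x - x0; fy <- y - y0
  m[y0, x0] * (1 - fx) * (1 - fy) + m[y0, x0 + 1] * fx * (1 - fy) +
    m[y0 + 1, x0] * (1 - fx) * fy + m[y0 + 1, x0 + 1] * fx * fy
}

# Bilinear resize by direct evaluation at the half-pixel target centers.
oracleResize <- function(m, outH, outW) {
  out <- matrix(0, outH, outW)
  for (i in seq_len(outH)) for (j in seq_len(outW)) {
    sy <- min(max((i - 0.5) * nrow(m) / outH + 0.5, 1), nrow(m))
    sx <- min(max((j - 0.5) * ncol(m) / outW + 0.5, 1), ncol(m))
    out[i, j] <- oracleBilinearAt(m, sx, sy)
  }
  out
}

# Literal per-pixel circular LBP: for every interior center, threshold the
# P interpolated circle samples and accumulate 2^p bits; pool into uniform
# bins by counting circular transitions; normalize per cell.
oracleLBP <- function(img, R, P, gridN = 1L) {
  H <- nrow(img); W <- ncol(img)
  cr <- ceiling(R)
  nBins <- P * (P - 1) + 3
  # uniform bin of a code: rank among uniform codes, else catch-all
  transitions <- function(code) {
    bits <- as.integer(intToBits(code))[1:P]
    sum(bits != c(bits[-1], bits[1]))
  }
  uniCodes <- Filter(function(cd) transitions(cd) <= 2, 0:(2^P - 1))
  binOf <- function(code) {
    k <- match(code, uniCodes)
    if (is.na(k)) nBins else k
  }
  hist <- matrix(0, gridN * gridN, nBins)
  for (yc in (cr + 1):(H - cr)) for (xc in (cr + 1):(W - cr)) {
    ic <- img[yc, xc]
    code <- 0
    for (p in 0:(P - 1)) {
      xp <- xc + R * cos(2 * pi * p / P)
      yp <- yc - R * sin(2 * pi * p / P)
      ip <- oracleBilinearAt(img, xp, yp)
      if (ip - ic >= -1e-9) code <- code + 2^p
    }
    cellR <- min(floor((yc - 1) / (H / gridN)), gridN - 1)
    cellC <- min(floor((xc - 1) / (W / gridN)), gridN - 1)
    cell <- cellR * gridN + cellC + 1
    b <- binOf(code)
    hist[cell, b] <- hist[cell, b] + 1
  }
  for (cell in seq_len(nrow(hist)))
    if (sum(hist[cell, ]) > 0) hist[cell, ] <- hist[cell, ] / sum(hist[cell, ])
  as.numeric(t(hist))
}

# Literal per-pixel HOG with the package's stated conventions: [0,1]
# intensity scaling, replicated-edge central differences, unsigned angles,
# linear votes between the two nearest of 9 bin centers at (k - 1/2) * 20
# degrees, 2x2-cell blocks with 1-cell stride, L2-eps normalization,
# row-major block and cell order.
oracleHOG <- function(img, C, nBins = 9, blockCells = 2, stride = 1,
                      eps = 1e-3) {
  img <- img / 255
  H <- nrow(img); W <- ncol(img)
  at <- function(i, j) img[min(max(i, 1), H), min(max(j, 1), W)]
  nR <- H %/% C; nC <- W %/% C
  hists <- array(0, c(nR, nC, nBins))
  w <- 180 / nBins
  for (y in 1:H) for (x in 1:W) {
    gx <- at(y, x + 1) - at(y, x - 1)
    gy <- at(y + 1, x) - at(y - 1, x)
    mag <- sqrt(gx^2 + gy^2)
    ang <- (atan2(gy, gx) * 180 / pi) %% 180
    b <- ang / w - 0.5
    b0 <- floor(b)
    w1 <- 1 - (b - b0)
    i0 <- (b0 %% nBins) + 1
    i1 <- ((b0 + 1) %% nBins) + 1
    cr <- (y - 1) %/% C + 1; cc <- (x - 1) %/% C + 1
    hists[cr, cc, i0] <- hists[cr, cc, i0] + mag * w1
    hists[cr, cc, i1] <- hists[cr, cc, i1] + mag * (1 - w1)
  }
  out <- c()
  for (br in seq_len((nR - blockCells) %/% stride + 1)) {
    for (bc in seq_len((nC - blockCells) %/% stride + 1)) {
      v <- c()
      for (cr in seq_len(blockCells)) for (cc in seq_len(blockCells))
        v <- c(v, hists[(br - 1) * stride + cr, (bc - 1) * stride + cc, ])
      out <- c(out, v / sqrt(sum(v^2) + eps^2))
    }
  }
  out
}

# Random grayscale test image with reproducible values in [0, 255].
randomGray <- function(side, seed = 1) {
  set.seed(seed)
  matrix(runif(side * side, 0, 255), side, side)
}

# Small high-separation synthetic fixture shared by several suites.
separableFixture <- function(n = 12, seed = 3, side = 96) {
  generateBeakDataset(SynthConfig(nPerClass = n, imageSide = side,
                                  views = "upper", shapeSeparation = 0.9,
                                  textureSeparation = 0.9, seed = seed))
}
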