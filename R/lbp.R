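#' Circular LBP sampling positions
#'
#' Coordinates of the P sampling points on the circle of radius R around a
#' center, in index order p = 0...P-1: point p lies at
#' (x_c + R cos(2 pi p / P), y_c - R sin(2 pi p / P)); the minus sign
#' reflects the image y-axis pointing down and fixes the bit order of the
#' code.
#'
#' @param center numeric 2-vector (x, y) of the center pixel.
#' @param config an \linkS4class{LBPConfig}.
#' @return P x 2 matrix with columns x, y.
#' @examples
#' samplePositions(c(10, 10), LBPConfig(R = 1, P = 8))
#' @export
samplePositions <- function(center, config) {
  p <- seq_len(config@P) - 1
  ang <- 2 * pi * p / config@P
  cbind(x = center[1] + config@R * cos(ang),
        y = center[2] - config@R * sin(ang))
}

# Per-point circle offsets with precomputed bilinear corner weights.
lbpOffsets <- function(config) {
  p <- seq_len(config@P) - 1
  ang <- 2 * pi * p / config@P
  dx <- config@R * cos(ang)
  dy <- -config@R * sin(ang)
  # snap near-integer offsets so exact lattice samples are exact
  dx <- ifelse(abs(dx - round(dx)) < 1e-9, round(dx), dx)
  dy <- ifelse(abs(dy - round(dy)) < 1e-9, round(dy), dy)
  x0 <- floor(dx); y0 <- floor(dy)
  list(x0 = x0, y0 = y0, fx = dx - x0, fy = dy - y0)
}

#' LBP code of a single center pixel
#'
#' Thresholds the P interpolated circle samples against the center
#' intensity: code = sum over p of 2^p * S(i_p - i_c) with S(x) = 1 iff
#' x >= 0 (so equal neighbors count as 1, which makes the code invariant
#' to adding a constant to the image). Fractional sampling coordinates are
#' resolved by bilinear interpolation of the four surrounding pixels.
#'
#' @param img grayscale pixel matrix.
#' @param center numeric 2-vector (x, y); must be at least R away from
#'   every border.
#' @param config an \linkS4class{LBPConfig}.
#' @return integer code in [0, 2^P).
#' @examples
#' lbpCode(matrix(5, 5, 5), c(3, 3), LBPConfig())  # constant -> 2^P - 1
#' @export
lbpCode <- function(img, center, config) {
  pos <- samplePositions(center, config)
  ic <- img[center[2], center[1]]
  vals <- bilinearSample(img, pos[, "y"], pos[, "x"])
  # S(x) = 1 iff x >= 0, with a tolerance absorbing bilinear rounding so
  # that exactly-equal neighbors (e.g. constant images) threshold as equal
  sum(2^(seq_len(config@P) - 1) * (vals - ic >= -1e-9))
}

# Number of circular 0/1 transitions of code under P bits.
lbpTransitions <- function(code, P) {
  bits <- (code %/% 2^(0:(P - 1))) %% 2
  sum(bits != bits[c(2:P, 1)])
}

# Uniform-pattern lookup: maps each code 0..2^P-1 to a bin in 1..P(P-1)+3.
# Uniform codes (<= 2 transitions) get dedicated bins in ascending code
# order; all other codes share the final catch-all bin.
uniformLookup <- function(P) {
  P <- as.integer(P)
  codes <- 0:(2^P - 1)
  tr <- vapply(codes, lbpTransitions, 0, P = P)
  uni <- codes[tr <= 2]
  nb <- P * (P - 1) + 3L
  lut <- rep.int(nb, 2^P)
  lut[uni + 1L] <- seq_along(uni)
  as.integer(lut)
}

#' Uniform-pattern bin of an LBP code
#'
#' Codes with at most two circular 0/1 transitions are "uniform" and each
#' receives a dedicated bin (there are P(P-1)+2 of them); all remaining
#' codes share one catch-all bin, for P(P-1)+3 bins in total (59 at P = 8).
#'
#' @param code integer in [0, 2^P).
#' @param P number of sampling points.
#' @return bin index in 1..P(P-1)+3.
#' @examples
#' uniformBin(0, 8); uniformBin(255, 8)
#' @export
uniformBin <- function(code, P) {
  if (any(code < 0 | code >= 2^P)) stop("code out of [0, 2^P)")
  uniformLookup(P)[code + 1L]
}

#' Number of LBP histogram bins
#'
#' P(P-1)+3 under the uniform mapping, 2^P otherwise.
#'
#' @param config an \linkS4class{LBPConfig}.
#' @export
lbpNBins <- function(config) {
  if (config@uniform) config@P * (config@P - 1L) + 3L else 2L^config@P
}

# Code matrix for all valid centers (those at least ceiling(R) from every
# border; border centers are skipped, no padding). Vectorized: each of the
# P samples is one bilinear blend of four shifted submatrices.
lbpCodeMatrix <- function(img, config) {
  H <- nrow(img); W <- ncol(img)
  cr <- as.integer(ceiling(config@R))
  if (H < 2L * cr + 1L || W < 2L * cr + 1L)
    stop("image smaller than the LBP neighborhood (side < 2R+1)")
  rows <- (cr + 1L):(H - cr)
  cols <- (cr + 1L):(W - cr)
  ic <- img[rows, cols, drop = FALSE]
  off <- lbpOffsets(config)
  code <- matrix(0, length(rows), length(cols))
  for (p in seq_len(config@P)) {
    y0 <- off$y0[p]; x0 <- off$x0[p]; fy <- off$fy[p]; fx <- off$fx[p]
    v <- (1 - fy) * (1 - fx) * img[rows + y0, cols + x0, drop = FALSE]
    if (fy > 0) v <- v + fy * (1 - fx) * img[rows + y0 + 1L, cols + x0, drop = FALSE]
    if (fx > 0) v <- v + (1 - fy) * fx * img[rows + y0, cols + x0 + 1L, drop = FALSE]
    if (fy > 0 && fx > 0)
      v <- v + fy * fx * img[rows + y0 + 1L, cols + x0 + 1L, drop = FALSE]
    code <- code + 2^(p - 1) * (v - ic >= -1e-9)  # same tolerance as lbpCode
  }
  list(code = code, rows = rows, cols = cols)
}

#' Circular uniform LBP descriptor
#'
#' Computes the LBP code of every interior pixel (centers closer than R to
#' an edge are skipped), pools codes into uniform-pattern bins, divides the
#' image into \code{gridN} x \code{gridN} cells, normalizes each cell's
#' histogram to sum 1 and concatenates the cells in row-major order. The
#' descriptor length is gridN^2 * (P(P-1)+3); with the default single
#' global cell and P = 8 this is the canonical 59-dimensional texture
#' vector.
#'
#' @param img grayscale pixel matrix (use \code{\link{toGrayResized}} with
#'   side 512 for the study geometry), at least (2R+1) x (2R+1).
#' @param config an \linkS4class{LBPConfig}.
#' @return numeric feature vector with attribute \code{tag = "lbp"}.
#' @examples
#' length(lbpDescriptor(matrix(runif(1024, 0, 255), 32), LBPConfig()))  # 59
#' @export
lbpDescriptor <- function(img, config = LBPConfig()) {
  validObject(config)
  cm <- lbpCodeMatrix(img, config)
  nb <- lbpNBins(config)
  bins <- if (config@uniform)
    matrix(uniformLookup(config@P)[cm$code + 1L], nrow(cm$code))
  else cm$code + 1L
  H <- nrow(img); W <- ncol(img); g <- config@gridN
  cellR <- pmin(floor((cm$rows - 1L) / (H / g)), g - 1L)  # 0-based cell row
  cellC <- pmin(floor((cm$cols - 1L) / (W / g)), g - 1L)
  # row-major cell order: cell index = cellR * g + cellC
  cellIdx <- outer(cellR * g, cellC, "+")
  key <- cellIdx * nb + (bins - 1L)
  counts <- tabulate(key + 1L, nbins = g * g * nb)
  out <- numeric(g * g * nb)
  for (cell in seq_len(g * g) - 1L) {
    h <- counts[cell * nb + seq_len(nb)]
    s <- sum(h)
    out[cell * nb + seq_len(nb)] <- if (s > 0) h / s else h
  }
  attr(out, "tag") <- "lbp"
  out
}
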