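#' Image gradients by central differences
#'
#' G_x(x, y) = I(x+1, y) - I(x-1, y) and G_y(x, y) = I(x, y+1) - I(x, y-1)
#' with edge replication at the borders; magnitude is the Euclidean norm
#' and the angle is resolved to the full quadrant with the two-argument
#' arctangent (degrees), folded to [0, 180) when \code{signed = FALSE}.
#'
#' @param img grayscale pixel matrix, side >= 3.
#' @param signed keep the full [0, 360) range if TRUE.
#' @return list with matrices \code{magnitude} and \code{angle} (degrees).
#' @examples
#' g <- gradients(matrix(rep(1:8, each = 8), 8))  # horizontal ramp
#' g$magnitude[4, 4]; g$angle[4, 4]
#' @export
gradients <- function(img, signed = FALSE) {
  H <- nrow(img); W <- ncol(img)
  if (H < 3L || W < 3L) stop("image must be at least 3 x 3")
  gx <- img[, c(2:W, W), drop = FALSE] - img[, c(1, 1:(W - 1)), drop = FALSE]
  gy <- img[c(2:H, H), , drop = FALSE] - img[c(1, 1:(H - 1)), , drop = FALSE]
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) * 180 / pi
  ang <- if (signed) ang %% 360 else ang %% 180
  list(magnitude = mag, angle = ang)
}

#' Per-cell orientation histograms
#'
#' Divides the gradient grids into cells of \code{cellPx} x \code{cellPx}
#' pixels and accumulates magnitude-weighted votes into \code{nBins}
#' orientation bins, splitting each vote linearly between the two nearest
#' bin centers (circular over the orientation range). Bin k (1-based) is
#' centered at (k - 1/2) * range/nBins.
#'
#' @param mag,angle matrices from \code{\link{gradients}}; their shape must
#'   be divisible by \code{cellPx}.
#' @param config an \linkS4class{HOGConfig}.
#' @return array of dim (cells per row, cells per col, nBins); cell (i, j)
#'   covers pixel rows/cols ((i-1)*C+1):(i*C).
#' @export
cellHistograms <- function(mag, angle, config) {
  validObject(config)
  H <- nrow(mag); W <- ncol(mag)
  C <- config@cellPx; nb <- config@nBins
  if (!identical(dim(mag), dim(angle))) stop("gradient grids differ in shape")
  if (H %% C != 0L || W %% C != 0L)
    stop("image shape ", H, " x ", W, " not divisible by cell size ", C)
  rangeDeg <- if (config@signed) 360 else 180
  w <- rangeDeg / nb
  b <- angle / w - 0.5            # fractional bin position
  b0 <- floor(b)
  w1 <- 1 - (b - b0)
  i0 <- (as.integer(b0) %% nb)    # 0-based bins
  i1 <- (i0 + 1L) %% nb
  cellR <- (seq_len(H) - 1L) %/% C          # 0-based cell coordinates
  cellC <- (seq_len(W) - 1L) %/% C
  nR <- H %/% C; nC <- W %/% C
  cellIdx <- outer(cellR, cellC * nR, "+")  # column-major cell index
  key0 <- cellIdx + (nR * nC) * i0
  key1 <- cellIdx + (nR * nC) * i1
  tot <- nR * nC * nb
  votes <- unname(rowsum(c(mag * w1, mag * (1 - w1)),
                         group = c(key0, key1)))
  counts <- numeric(tot)
  counts[sort(unique(c(key0, key1))) + 1L] <- votes
  array(counts, dim = c(nR, nC, nb))
}

#' HOG descriptor length
#'
#' ((side/C - blockCells)/stride + 1)^2 * blockCells^2 * nBins.
#'
#' @param side input image side in pixels.
#' @param config an \linkS4class{HOGConfig}.
#' @export
hogLength <- function(side, config) {
  ncell <- as.integer(side) %/% config@cellPx
  nblk <- (ncell - config@blockCells) %/% config@blockStrideCells + 1L
  as.integer(nblk^2 * config@blockCells^2 * config@nBins)
}

#' Histogram-of-oriented-gradients descriptor
#'
#' Intensities are scaled to [0, 1], gradients taken by central
#' differences, magnitude-weighted orientation votes pooled into cells,
#' and blocks of \code{blockCells} x \code{blockCells} cells (sliding by
#' \code{blockStrideCells}) are L2-normalized with the
#' \code{blockNormEps} guard and concatenated in row-major block order
#' (cells row-major within each block). With the default geometry (9
#' unsigned bins, 2 x 2-cell blocks, 1-cell stride) a 256 x 256 image
#' yields 8100 dimensions at C = 16, 1764 at C = 32 and 324 at C = 64.
#'
#' @param img grayscale pixel matrix in [0, 255]; its side must be
#'   divisible by \code{cellPx} (use \code{\link{toGrayResized}} with side
#'   256 for the study geometry).
#' @param config an \linkS4class{HOGConfig}.
#' @return numeric feature vector with attribute \code{tag = "hog"}.
#' @examples
#' length(hogDescriptor(matrix(runif(256^2, 0, 255), 256),
#'                      HOGConfig(cellPx = 64)))  # 324
#' @export
hogDescriptor <- function(img, config = HOGConfig()) {
  validObject(config)
  g <- gradients(img / 255, signed = config@signed)
  hists <- cellHistograms(g$magnitude, g$angle, config)
  nR <- dim(hists)[1]; nC <- dim(hists)[2]; nb <- config@nBins
  bc <- config@blockCells; st <- config@blockStrideCells
  if (nR < bc || nC < bc)
    stop("fewer cells (", nR, ") than blockCells (", bc, ") per side")
  nbR <- (nR - bc) %/% st + 1L
  nbC <- (nC - bc) %/% st + 1L
  eps2 <- config@blockNormEps^2
  out <- numeric(nbR * nbC * bc * bc * nb)
  blockLen <- bc * bc * nb
  k <- 0L
  for (br in seq_len(nbR)) {
    for (bcol in seq_len(nbC)) {
      r0 <- (br - 1L) * st; c0 <- (bcol - 1L) * st
      v <- numeric(blockLen)
      j <- 0L
      for (cr in seq_len(bc)) for (cc in seq_len(bc)) {  # cells row-major
        v[j + seq_len(nb)] <- hists[r0 + cr, c0 + cc, ]
        j <- j + nb
      }
      out[k + seq_len(blockLen)] <- v / sqrt(sum(v^2) + eps2)
      k <- k + blockLen
    }
  }
  attr(out, "tag") <- "hog"
  out
}
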