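# Internal numeric helpers shared by the image modules.

clip01 <- function(x, lo = 0, hi = 255) pmin(pmax(x, lo), hi)

# Bilinear sample of matrix `m` at fractional (row, col) coordinates.
# Coordinates are 1-based; callers guarantee they are within [1, nrow/ncol]
# unless `fill` is given, in which case out-of-range samples return `fill`.
bilinearSample <- function(m, rows, cols, fill = NULL) {
  H <- nrow(m); W <- ncol(m)
  if (!is.null(fill)) {
    out <- rep(fill, length(rows))
    ok <- rows >= 1 & rows <= H & cols >= 1 & cols <= W
    if (!any(ok)) return(out)
    out[ok] <- bilinearSample(m, rows[ok], cols[ok])
    return(out)
  }
  r0 <- pmin(floor(rows), H - 1L); r0 <- pmax(r0, 1L)
  c0 <- pmin(floor(cols), W - 1L); c0 <- pmax(c0, 1L)
  fr <- rows - r0; fc <- cols - c0
  i00 <- (c0 - 1L) * H + r0
  v00 <- m[i00]; v10 <- m[i00 + 1L]
  v01 <- m[i00 + H]; v11 <- m[i00 + H + 1L]
  (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
    (1 - fr) * fc * v01 + fr * fc * v11
}

# Bilinear resize of a matrix to outH x outW, no antialiasing.
# Target pixel centers map to source coordinates via the half-pixel
# convention src = (dst - 0.5) * (inSize/outSize) + 0.5, clamped to the
# source grid; identical sizes reproduce the input exactly.
bilinearResize <- function(m, outH, outW) {
  H <- nrow(m); W <- ncol(m)
  sr <- clip01((seq_len(outH) - 0.5) * (H / outH) + 0.5, 1, H)
  sc <- clip01((seq_len(outW) - 0.5) * (W / outW) + 0.5, 1, W)
  rows <- rep(sr, times = outW)
  cols <- rep(sc, each = outH)
  matrix(bilinearSample(m, rows, cols), outH, outW)
}

# ITU-R 601 luminance. `p` is a matrix or HxWx3 array in [0,255].
toLuminance <- function(p) {
  if (length(dim(p)) == 2L) return(p)
  0.299 * p[, , 1] + 0.587 * p[, , 2] + 0.114 * p[, , 3]
}

# Derive a stream-specific child seed from a base seed, kept within the
# 32-bit integer range.
childSeed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 1103 * k) %% 2147483647)
}
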