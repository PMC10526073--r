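#' Affine warp of a grayscale image
#'
#' Applies the affine map y = omega x + b (coordinates (x, y) relative to
#' the image center, x right, y down) by inverse mapping: every output
#' pixel is bilinearly sampled from the source at omega^{-1}(y - b), and
#' coordinates falling outside the source are filled with the light-board
#' background value 255.
#'
#' @param img numeric pixel matrix (rows = y, cols = x) in [0, 255], or a
#'   \linkS4class{BeakImage} (RGB images are warped per channel).
#' @param omega invertible 2 x 2 matrix (the transformation weights).
#' @param b numeric 2-vector (the constant term), in pixels.
#' @param fill background fill value, default 255.
#' @return object of the same kind as \code{img}.
#' @examples
#' m <- matrix(1:9 * 20, 3)
#' identical(applyAffine(m, diag(2), c(0, 0)), m)
#' @export
applyAffine <- function(img, omega, b = c(0, 0), fill = 255) {
  if (is(img, "BeakImage")) {
    p <- img@pixels
    out <- if (length(dim(p)) == 3L) {
      q <- p
      for (ch in 1:3) q[, , ch] <- applyAffine(p[, , ch], omega, b, fill)
      q
    } else applyAffine(p, omega, b, fill)
    return(BeakImage(out, img@label, img@view, img@sourceId))
  }
  omega <- matrix(as.numeric(omega), 2, 2)
  if (abs(det(omega)) < 1e-12) stop("omega is singular")
  H <- nrow(img); W <- ncol(img)
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  u <- rep(seq_len(W) - cx, each = H)   # output x rel. to center
  v <- rep(seq_len(H) - cy, times = W)  # output y rel. to center
  inv <- solve(omega)
  sx <- inv[1, 1] * (u - b[1]) + inv[1, 2] * (v - b[2]) + cx
  sy <- inv[2, 1] * (u - b[1]) + inv[2, 2] * (v - b[2]) + cy
  # snap coordinates that are integers up to floating error, so that exact
  # permutations (flips, quarter rotations, integer shifts) stay exact
  sx <- ifelse(abs(sx - round(sx)) < 1e-9, round(sx), sx)
  sy <- ifelse(abs(sy - round(sy)) < 1e-9, round(sy), sy)
  out <- matrix(bilinearSample(img, sy, sx, fill = fill), H, W)
  clip01(out)  # guard against floating overshoot of the convex blend
}

#' Sample random affine augmentations of a training image
#'
#' Draws \code{nPerImage} augmented copies, each by composing (in order) an
#' optional horizontal flip, an aspect-ratio rescale, a rotation and a
#' random crop re-scaled to the original size, into a single affine map.
#' Labels and views are preserved; the draw is deterministic given
#' \code{spec@seed} and the image's source id.
#'
#' @param img a \linkS4class{BeakImage}.
#' @param spec an \linkS4class{AugmentSpec}.
#' @return list of \code{spec@nPerImage} \linkS4class{BeakImage}s with
#'   source ids \code{<id>_aug<k>}.
#' @examples
#' img <- BeakImage(matrix(runif(64, 0, 255), 8), "a")
#' length(sampleAugmentations(img, AugmentSpec(nPerImage = 2L)))
#' @export
sampleAugmentations <- function(img, spec) {
  validObject(spec)
  n <- spec@nPerImage
  if (n == 0L) return(list())
  d <- dim(img@pixels)
  set.seed(childSeed(spec@seed,
                     sum(utf8ToInt(img@sourceId)) %% 100000L))
  out <- vector("list", n)
  for (k in seq_len(n)) {
    flip <- runif(1) < spec@pFlip
    Fm <- if (flip) diag(c(-1, 1)) else diag(2)
    a <- runif(1, spec@aspectRange[1], spec@aspectRange[2])
    Am <- diag(c(sqrt(a), 1 / sqrt(a)))
    th <- runif(1, spec@rotationRangeDeg[1], spec@rotationRangeDeg[2]) * pi / 180
    Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    f <- runif(1, spec@cropFracRange[1], spec@cropFracRange[2])
    s <- 1 / f
    half <- min(d[1], d[2]) / 2
    slack <- half * (1 - f)
    bc <- runif(2, -slack, slack)  # crop-box center rel. to image center
    omega <- s * (Rm %*% Am %*% Fm)
    b <- -s * bc
    aug <- applyAffine(img, omega, b)
    aug@sourceId <- sprintf("%s_aug%d", img@sourceId, k)
    out[[k]] <- aug
  }
  out
}
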