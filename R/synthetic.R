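# Synthetic beak-image generator: parametric hooked-wedge silhouettes on a
# light board, with class-specific contour geometry (morphology signal) and
# class-specific pigmentation striping (texture signal).

# Per-class generating parameters. The contour is the polar curve
# r(theta) = a * (1 + elong*cos(theta) + curv*cos(2*theta + 0.7)); `elong`
# plays the role of the hood/crest length asymmetry and `curv` of the hook
# curvature. Texture is a sinusoidal pigment striping of period
# `stripePeriod` (pixels) and amplitude `stripeContrast`, at a random
# per-image orientation. Class spacing scales with the separations; at
# separation 0 all classes share one parameter set.
synthClassParams <- function(config) {
  k <- seq_along(config@classes)
  u <- (k - (length(k) + 1) / 2) / max((length(k) - 1) / 2, 1)  # in [-1, 1]
  w <- rep_len(c(-1, 1, 1, -1), length(k))
  s <- config@shapeSeparation
  t <- config@textureSeparation
  data.frame(
    class = config@classes,
    hoodCrestRatio = 0.30 + 0.20 * s * u,
    curvature = 0.18 + 0.12 * s * w,
    stripePeriod = config@imageSide * (0.020 + 0.011 * t * (k - 1)),
    stripeContrast = 30 + 8 * t * u)
}

#' Ground-truth parameter table of the synthetic classes
#'
#' One row per class with the contour parameters (hood/crest asymmetry,
#' hook curvature) and texture parameters (stripe period in pixels, stripe
#' contrast in intensity units) that generate it, for use in recovery
#' tests. Rows are distinct whenever the separations are positive and
#' identical at separation zero; stripe periods increase with
#' \code{textureSeparation}.
#'
#' @param config a \linkS4class{SynthConfig}.
#' @return a data.frame with one row per class.
#' @examples
#' describeGroundTruth(SynthConfig())
#' @export
describeGroundTruth <- function(config) {
  validObject(config)
  synthClassParams(config)
}

renderBeak <- function(side, params, view, noiseSd) {
  cx <- side * (0.5 + runif(1, -0.02, 0.02))
  cy <- side * (0.5 + runif(1, -0.02, 0.02))
  psi <- runif(1, -10, 10) * pi / 180
  sc <- runif(1, 0.92, 1.05)
  dx <- matrix(rep(seq_len(side) - cx, each = side), side)
  dy <- matrix(rep(seq_len(side) - cy, times = side), side)
  xr <- dx * cos(psi) + dy * sin(psi)
  yr <- -dx * sin(psi) + dy * cos(psi)
  if (view == "lower") xr <- -xr  # global reflection between views
  elong <- params$hoodCrestRatio * (if (view == "lower") 0.85 else 1)
  curv <- params$curvature
  theta <- atan2(yr, xr)
  rho <- sqrt(xr^2 + yr^2)
  fshape <- function(th) 1 + elong * cos(th) + curv * cos(2 * th + 0.7)
  thGrid <- seq(0, 2 * pi, length.out = 256L)
  a <- sc * side * 0.27 / sqrt(mean(fshape(thGrid)^2))  # area-normalized
  mask <- rho <= a * fshape(theta)
  shade <- pmin(pmax(xr / (1.6 * a), -1), 1)
  base <- 95 + 45 * shade  # hood-to-crest pigment gradient
  phi <- runif(1, 0, pi)   # stripe orientation: per-image nuisance
  phase <- runif(1, 0, 2 * pi)
  tex <- params$stripeContrast *
    sin(2 * pi * (xr * cos(phi) + yr * sin(phi)) / params$stripePeriod +
        phase)
  img <- matrix(255, side, side)
  img[mask] <- clip01(base[mask] + tex[mask])
  if (noiseSd > 0) img <- img + matrix(rnorm(side * side, 0, noiseSd), side)
  clip01(img)
}

#' Generate a labeled synthetic beak dataset
#'
#' Renders \code{nPerClass * length(classes) * length(views)} images: a
#' light background (around 255, emulating a white light board), a dark
#' hooked-wedge silhouette whose hood/crest asymmetry and curvature are
#' class-specific (spacing scaled by \code{shapeSeparation}), sinusoidal
#' pigment striping whose period and contrast are class-specific (spacing
#' scaled by \code{textureSeparation}; orientation is a random per-image
#' nuisance), and clipped Gaussian pixel noise. Pose (position, small
#' rotation, scale) is jittered per image. Generation is deterministic
#' given \code{config@seed}.
#'
#' @param config a \linkS4class{SynthConfig}.
#' @return list of \linkS4class{BeakImage}s with source ids
#'   \code{<class>_<view>_<index>}.
#' @examples
#' imgs <- generateBeakDataset(SynthConfig(nPerClass = 2, imageSide = 64))
#' length(imgs)
#' @export
generateBeakDataset <- function(config = SynthConfig()) {
  validObject(config)
  params <- synthClassParams(config)
  out <- vector("list",
                config@nPerClass * length(config@classes) *
                  length(config@views))
  j <- 0L
  for (ci in seq_along(config@classes)) {
    for (v in config@views) {
      for (i in seq_len(config@nPerClass)) {
        j <- j + 1L
        set.seed(childSeed(config@seed, j))
        px <- renderBeak(config@imageSide, params[ci, ], v, config@noiseSd)
        out[[j]] <- BeakImage(px, config@classes[ci], v,
                              sprintf("%s_%s_%03d", config@classes[ci], v, i))
      }
    }
  }
  out
}
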