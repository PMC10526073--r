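#' Batch shallow descriptors
#'
#' Computes the LBP or HOG descriptor of every image (after grayscale
#' conversion and bilinear resize to \code{side}) and assembles a
#' \linkS4class{FeatureSet}. The study geometry uses side 512 for LBP and
#' side 256 for HOG.
#'
#' @param imgs list of \linkS4class{BeakImage}s.
#' @param config an \linkS4class{LBPConfig} / \linkS4class{HOGConfig}.
#' @param side descriptor input side in pixels.
#' @return a \linkS4class{FeatureSet} tagged \code{"lbp"} / \code{"hog"}.
#' @export
lbpFeatures <- function(imgs, config = LBPConfig(), side = 512L) {
  vals <- vapply(imgs,
                 function(im) lbpDescriptor(toGrayResized(im, side), config),
                 numeric(config@gridN^2 * lbpNBins(config)))
  FeatureSet(matrix(vals, ncol = length(imgs)), "lbp",
             vapply(imgs, function(x) x@sourceId, ""),
             vapply(imgs, function(x) x@label, ""),
             vapply(imgs, function(x) x@view, ""))
}

#' @rdname lbpFeatures
#' @export
hogFeatures <- function(imgs, config = HOGConfig(), side = 256L) {
  vals <- vapply(imgs,
                 function(im) hogDescriptor(toGrayResized(im, side), config),
                 numeric(hogLength(side, config)))
  FeatureSet(matrix(vals, ncol = length(imgs)), "hog",
             vapply(imgs, function(x) x@sourceId, ""),
             vapply(imgs, function(x) x@label, ""),
             vapply(imgs, function(x) x@view, ""))
}
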