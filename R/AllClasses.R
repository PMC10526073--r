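#' @import methods
#' @importFrom stats rnorm runif sd var
NULL

setClassUnion("matrixOrArray", c("matrix", "array"))

#' Labeled beak image
#'
#' A single labeled image: a 2-D grayscale or 3-D RGB intensity grid with
#' values in [0, 255], a class label, a view (\code{"upper"} or
#' \code{"lower"}) and an opaque provenance identifier.
#'
#' @slot pixels numeric matrix (rows = y, columns = x) or H x W x 3 array,
#'   intensities in [0, 255].
#' @slot label character(1) class label.
#' @slot view character(1), \code{"upper"} or \code{"lower"}.
#' @slot sourceId character(1) provenance identifier, unique within a dataset.
#' @export
setClass("BeakImage", representation(
  pixels = "matrixOrArray",
  label = "character",
  view = "character",
  sourceId = "character"
))

setValidity("BeakImage", function(object) {
  p <- object@pixels
  d <- dim(p)
  if (!(length(d) == 2L || (length(d) == 3L && d[3] == 3L)))
    return("pixels must be a 2-D matrix or an H x W x 3 array")
  if (d[1] < 3L || d[2] < 3L)
    return("image must be at least 3 x 3 (descriptors need neighborhoods)")
  if (anyNA(p) || min(p) < 0 || max(p) > 255)
    return("pixel values must lie in [0, 255]")
  if (length(object@label) != 1L || length(object@sourceId) != 1L)
    return("label and sourceId must be single strings")
  if (length(object@view) != 1L || !object@view %in% c("upper", "lower"))
    return("view must be 'upper' or 'lower'")
  TRUE
})

#' @param pixels,label,view,sourceId see slots.
#' @rdname BeakImage-class
#' @export
BeakImage <- function(pixels, label, view = "upper", sourceId = label) {
  new("BeakImage", pixels = pixels, label = as.character(label),
      view = view, sourceId = as.character(sourceId))
}

setMethod("show", "BeakImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("BeakImage %s [%s/%s] %d x %d%s\n", object@sourceId,
              object@label, object@view, d[1], d[2],
              if (length(d) == 3L) " RGB" else " gray"))
})

#' Disjoint train/validation/test partition
#'
#' Holds the source ids of a stratified dataset split. Validity enforces
#' pairwise disjointness of the three sets.
#'
#' @slot train,val,test character vectors of source ids.
#' @export
setClass("DatasetSplit", representation(
  train = "character", val = "character", test = "character"
))

setValidity("DatasetSplit", function(object) {
  a <- object@train; b <- object@val; d <- object@test
  if (anyDuplicated(c(a, b, d)))
    return("train, val and test sets must be pairwise disjoint")
  TRUE
})

setMethod("show", "DatasetSplit", function(object) {
  cat(sprintf("DatasetSplit: %d train / %d val / %d test\n",
              length(object@train), length(object@val), length(object@test)))
})

#' Circular LBP descriptor configuration
#'
#' Geometry of the circular, interpolated local binary pattern: sampling
#' radius \code{R} (pixels), number of sampling points \code{P} on the
#' circle, and the number of cells per image side (\code{gridN}) whose
#' normalized histograms are concatenated. With \code{uniform = TRUE} codes
#' are pooled into the P(P-1)+3 uniform-pattern bins.
#'
#' @slot R numeric(1), radius > 0. Default 1.
#' @slot P integer(1), sampling points >= 4. Default 8.
#' @slot gridN integer(1), cells per side >= 1. Default 1 (one global
#'   histogram, giving the canonical 59-dimensional descriptor at P = 8).
#' @slot uniform logical(1).
#' @export
setClass("LBPConfig", representation(
  R = "numeric", P = "integer", gridN = "integer", uniform = "logical"
))

setValidity("LBPConfig", function(object) {
  if (object@R <= 0) return("R must be > 0")
  if (object@P < 4L) return("P must be >= 4")
  if (object@P > 16L) return("P must be <= 16 (2^P code table)")
  if (object@gridN < 1L) return("gridN must be >= 1")
  TRUE
})

#' @param R,P,gridN,uniform see slots.
#' @rdname LBPConfig-class
#' @export
LBPConfig <- function(R = 1, P = 8L, gridN = 1L, uniform = TRUE) {
  new("LBPConfig", R = as.numeric(R), P = as.integer(P),
      gridN = as.integer(gridN), uniform = uniform)
}

#' HOG descriptor configuration
#'
#' Cell/block geometry of the histogram-of-oriented-gradients descriptor:
#' square cells of \code{cellPx} pixels, blocks of \code{blockCells} x
#' \code{blockCells} cells sliding with \code{blockStrideCells}, and
#' \code{nBins} orientation bins over [0, 180) degrees (unsigned) or
#' [0, 360).
#'
#' @slot cellPx integer(1), cell side in pixels (>= 2). Default 16.
#' @slot blockCells integer(1), cells per block side. Default 2.
#' @slot blockStrideCells integer(1), block stride in cells. Default 1.
#' @slot nBins integer(1), orientation bins (>= 2). Default 9.
#' @slot signed logical(1); FALSE folds angles to [0, 180).
#' @slot blockNormEps numeric(1), small positive constant in the block L2
#'   normalization guard.
#' @export
setClass("HOGConfig", representation(
  cellPx = "integer", blockCells = "integer", blockStrideCells = "integer",
  nBins = "integer", signed = "logical", blockNormEps = "numeric"
))

setValidity("HOGConfig", function(object) {
  if (object@cellPx < 2L) return("cellPx must be >= 2")
  if (object@nBins < 2L) return("nBins must be >= 2")
  if (object@blockCells < 1L || object@blockStrideCells < 1L)
    return("blockCells and blockStrideCells must be >= 1")
  if (object@blockNormEps <= 0) return("blockNormEps must be > 0")
  TRUE
})

#' @param cellPx,blockCells,blockStrideCells,nBins,signed,blockNormEps see slots.
#' @rdname HOGConfig-class
#' @export
HOGConfig <- function(cellPx = 16L, blockCells = 2L, blockStrideCells = 1L,
                      nBins = 9L, signed = FALSE, blockNormEps = 1e-3) {
  new("HOGConfig", cellPx = as.integer(cellPx),
      blockCells = as.integer(blockCells),
      blockStrideCells = as.integer(blockStrideCells),
      nBins = as.integer(nBins), signed = signed,
      blockNormEps = blockNormEps)
}

#' Augmentation specification
#'
#' Parameters of the affine training-set augmentation: random horizontal
#' flip, rotation, random crop (re-resized to the original size) and
#' aspect-ratio rescale, composed into a single affine map per sample.
#'
#' @slot pFlip numeric(1) flip probability in [0, 1].
#' @slot rotationRangeDeg numeric(2) closed rotation interval in degrees.
#' @slot cropFracRange numeric(2) crop side fraction interval in (0, 1].
#' @slot aspectRange numeric(2) width/height rescale interval.
#' @slot nPerImage integer(1) augmented copies per source image (>= 0).
#' @slot seed integer(1).
#' @export
setClass("AugmentSpec", representation(
  pFlip = "numeric", rotationRangeDeg = "numeric", cropFracRange = "numeric",
  aspectRange = "numeric", nPerImage = "integer", seed = "integer"
))

setValidity("AugmentSpec", function(object) {
  if (object@pFlip < 0 || object@pFlip > 1) return("pFlip must be in [0,1]")
  if (length(object@rotationRangeDeg) != 2L ||
      diff(object@rotationRangeDeg) < 0) return("bad rotation range")
  if (length(object@cropFracRange) != 2L || object@cropFracRange[1] <= 0 ||
      object@cropFracRange[2] > 1 || diff(object@cropFracRange) < 0)
    return("cropFracRange must be an interval within (0, 1]")
  if (length(object@aspectRange) != 2L || object@aspectRange[1] <= 0 ||
      diff(object@aspectRange) < 0) return("bad aspectRange")
  if (object@nPerImage < 0L) return("nPerImage must be >= 0")
  TRUE
})

#' @param pFlip,rotationRangeDeg,cropFracRange,aspectRange,nPerImage,seed see slots.
#' @rdname AugmentSpec-class
#' @export
AugmentSpec <- function(pFlip = 0.5, rotationRangeDeg = c(-45, 45),
                        cropFracRange = c(0.7, 1), aspectRange = c(0.8, 1.25),
                        nPerImage = 1L, seed = 1L) {
  new("AugmentSpec", pFlip = pFlip, rotationRangeDeg = as.numeric(rotationRangeDeg),
      cropFracRange = as.numeric(cropFracRange),
      aspectRange = as.numeric(aspectRange),
      nPerImage = as.integer(nPerImage), seed = as.integer(seed))
}

#' Deep backbone configuration
#'
#' Architecture and training hyper-parameters of the convolutional backbone.
#' Profile \code{"reference50"} is the 50-layer bottleneck residual network
#' (stages 3,4,6,3; 2048-dimensional pooled penultimate feature, 224 x 224
#' input). Profile \code{"deskSmall"} is a shallow residual network (5
#' convolutions) with a configurable pooled dimension, sized so that the
#' full pipeline trains in seconds on a single CPU.
#'
#' @slot profile character(1), \code{"reference50"} or \code{"deskSmall"}.
#' @slot inputSide integer(1), input image side in pixels.
#' @slot nClasses integer(1).
#' @slot pooledDim integer(1), penultimate feature length of deskSmall
#'   (reference50 is fixed at 2048).
#' @slot epochs integer(1) (default 100), batchSize integer(1) (default 16).
#' @slot batchSize integer(1).
#' @slot lrSchedule 3-column matrix (fromEpoch, toEpoch, rate); default
#'   rate 1e-3 for epochs 1-50 and 1e-4 for 51-100.
#' @slot momentum numeric(1), SGD momentum.
#' @slot seed integer(1), weight-initialization seed.
#' @export
setClass("BackboneConfig", representation(
  profile = "character", inputSide = "integer", nClasses = "integer",
  pooledDim = "integer", epochs = "integer", batchSize = "integer",
  lrSchedule = "matrix", momentum = "numeric", seed = "integer"
))

setValidity("BackboneConfig", function(object) {
  if (!object@profile %in% c("reference50", "deskSmall"))
    return(sprintf("unknown profile '%s'", object@profile))
  if (object@inputSide < 8L) return("inputSide too small")
  if (object@epochs < 1L) return("epochs must be >= 1")
  if (object@batchSize < 1L) return("batchSize must be >= 1")
  if (object@nClasses < 2L) return("nClasses must be >= 2")
  if (ncol(object@lrSchedule) != 3L || any(object@lrSchedule[, 3] <= 0))
    return("lrSchedule must be (from, to, rate > 0) rows")
  TRUE
})

#' @param profile,inputSide,nClasses,pooledDim,epochs,batchSize,lrSchedule,momentum,seed see slots.
#' @rdname BackboneConfig-class
#' @export
BackboneConfig <- function(profile = c("reference50", "deskSmall"),
                           inputSide = 224L, nClasses = 4L, pooledDim = 64L,
                           epochs = 100L, batchSize = 16L,
                           lrSchedule = rbind(c(1, 50, 1e-3), c(51, 100, 1e-4)),
                           momentum = 0.9, seed = 1L) {
  profile <- match.arg(profile)
  new("BackboneConfig", profile = profile, inputSide = as.integer(inputSide),
      nClasses = as.integer(nClasses), pooledDim = as.integer(pooledDim),
      epochs = as.integer(epochs), batchSize = as.integer(batchSize),
      lrSchedule = lrSchedule, momentum = momentum, seed = as.integer(seed))
}

#' Residual convolutional backbone
#'
#' Wraps the layer graph, its configuration, the class order seen at
#' training time, the per-epoch loss history and the trained flag.
#'
#' @slot net list, internal layer graph.
#' @slot config \linkS4class{BackboneConfig}.
#' @slot featureDim integer(1), pooled penultimate feature length.
#' @slot classOrder character, label order of the output layer.
#' @slot trained logical(1).
#' @slot history data.frame with epoch, trainLoss, valLoss, valAcc, lr.
#' @export
setClass("BeakBackbone", representation(
  net = "list", config = "BackboneConfig", featureDim = "integer",
  classOrder = "character", trained = "logical", history = "data.frame"
))

setMethod("show", "BeakBackbone", function(object) {
  cat(sprintf("BeakBackbone [%s] input %dx%d, feature dim %d, %s\n",
              object@config@profile, object@config@inputSide,
              object@config@inputSide, object@featureDim,
              if (object@trained) sprintf("trained (%d epochs)",
                                          nrow(object@history))
              else "untrained"))
})

#' SVM classifier configuration
#'
#' Radial-basis-kernel maximum-margin classifier settings: penalty
#' \code{C = 10} and a one-vs-rest decomposition. \code{gamma = NA} selects
#' the variance-scaled heuristic 1/(d * Var(X)) on the (standardized)
#' training matrix.
#'
#' @slot kernel character(1), only \code{"rbf"}.
#' @slot cost numeric(1) penalty (the usual C) > 0, default 10.
#' @slot gamma numeric(1), RBF width; NA = 1/(d * Var) heuristic.
#' @slot standardize logical(1), per-dimension location/scale from the
#'   training data only. Default TRUE.
#' @export
setClass("SVMConfig", representation(
  kernel = "character", cost = "numeric", gamma = "numeric",
  standardize = "logical"
))

setValidity("SVMConfig", function(object) {
  if (object@kernel != "rbf") return("only the 'rbf' kernel is supported")
  if (object@cost <= 0) return("C must be > 0")
  if (!is.na(object@gamma) && object@gamma <= 0)
    return("gamma must be > 0 (or NA for the variance heuristic)")
  TRUE
})

#' @param kernel,gamma,standardize see slots.
#' @param C penalty, stored in the \code{cost} slot.
#' @rdname SVMConfig-class
#' @export
SVMConfig <- function(kernel = "rbf", C = 10, gamma = NA_real_,
                      standardize = TRUE) {
  new("SVMConfig", kernel = kernel, cost = C, gamma = as.numeric(gamma),
      standardize = standardize)
}

#' Trained one-vs-rest SVM classifier
#'
#' One binary RBF machine per class; prediction is the argmax of the
#' oriented decision values, ties broken by class order.
#'
#' @slot machines list of e1071 svm fits, one per class.
#' @slot signs numeric, +/-1 orientation of each machine's decision value.
#' @slot classOrder character.
#' @slot center,scale numeric, training standardization (length = feature dim).
#' @slot gamma numeric(1), the RBF width actually used.
#' @slot config \linkS4class{SVMConfig}.
#' @slot featureDim integer(1).
#' @slot tag character(1), feature provenance tag the model was fit on.
#' @export
setClass("BeakClassifier", representation(
  machines = "list", signs = "numeric", classOrder = "character",
  center = "numeric", scale = "numeric", gamma = "numeric",
  config = "SVMConfig", featureDim = "integer", tag = "character"
))

setMethod("show", "BeakClassifier", function(object) {
  cat(sprintf(
    "BeakClassifier: %d-class OVR rbf SVM (C = %g, gamma = %.4g) on %d-d '%s' features\n",
    length(object@classOrder), object@config@cost, object@gamma,
    object@featureDim, object@tag))
})

#' Confusion matrix
#'
#' K x K counts with rows = true class, columns = predicted class.
#'
#' @slot counts integer matrix.
#' @slot classOrder character, row/column label order.
#' @export
setClass("ConfusionMatrix", representation(
  counts = "matrix", classOrder = "character"
))

setValidity("ConfusionMatrix", function(object) {
  k <- length(object@classOrder)
  if (!all(dim(object@counts) == c(k, k)))
    return("counts must be K x K for K = length(classOrder)")
  if (any(object@counts < 0)) return("counts must be non-negative")
  TRUE
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat("ConfusionMatrix (rows = truth, cols = predicted)\n")
  print(object@counts)
})

#' Per-class and aggregate classification metrics
#'
#' Accuracy, precision, recall and F1 per class (one-vs-rest) and as a
#' macro (unweighted) aggregate, plus overall accuracy = trace/total.
#'
#' @slot perClass data.frame: class, accuracy, precision, recall, f1.
#' @slot aggregate named numeric: accuracy, precision, recall, f1.
#' @export
setClass("MetricsReport", representation(
  perClass = "data.frame", aggregate = "numeric"
))

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport\n aggregate:",
      paste(sprintf("%s=%.4f", names(object@aggregate), object@aggregate),
            collapse = " "), "\n")
  print(object@perClass, digits = 4)
})

#' Synthetic beak dataset configuration
#'
#' Conditions of the synthetic study: four squid species whose beak-like
#' silhouettes differ in contour geometry (hood/crest asymmetry and hook
#' curvature -- the morphology signal) and whose intra-silhouette
#' pigmentation differs in stripe period and contrast (the texture signal),
#' rendered dark on a light board with Gaussian pixel noise. Difficulty is
#' controlled by \code{shapeSeparation} and \code{textureSeparation} in
#' [0, 1]; at 0 the class-conditional distributions coincide.
#'
#' @slot nPerClass integer(1) images per class per view.
#' @slot classes character, class labels (default the four study species).
#' @slot views character subset of c("upper", "lower").
#' @slot imageSide integer(1), default 512.
#' @slot shapeSeparation,textureSeparation numeric(1) in [0, 1], default 0.8.
#' @slot noiseSd numeric(1) Gaussian pixel noise sd (intensity units),
#'   default 5.
#' @slot seed integer(1).
#' @export
setClass("SynthConfig", representation(
  nPerClass = "integer", classes = "character", views = "character",
  imageSide = "integer", shapeSeparation = "numeric",
  textureSeparation = "numeric", noiseSd = "numeric", seed = "integer"
))

setValidity("SynthConfig", function(object) {
  if (object@nPerClass < 1L) return("nPerClass must be >= 1")
  if (object@imageSide < 32L) return("imageSide must be >= 32")
  if (object@shapeSeparation < 0 || object@shapeSeparation > 1 ||
      object@textureSeparation < 0 || object@textureSeparation > 1)
    return("separations must be in [0, 1]")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (!all(object@views %in% c("upper", "lower")) || !length(object@views))
    return("views must be a non-empty subset of upper/lower")
  if (anyDuplicated(object@classes)) return("classes must be distinct")
  TRUE
})

#' @param nPerClass,classes,views,imageSide,shapeSeparation,textureSeparation,noiseSd,seed see slots.
#' @rdname SynthConfig-class
#' @export
SynthConfig <- function(nPerClass = 50L,
                        classes = c("D_gigas", "I_argentinus",
                                    "E_luminosa", "O_bartramii"),
                        views = c("upper", "lower"), imageSide = 512L,
                        shapeSeparation = 0.8, textureSeparation = 0.8,
                        noiseSd = 5, seed = 1L) {
  new("SynthConfig", nPerClass = as.integer(nPerClass), classes = classes,
      views = views, imageSide = as.integer(imageSide),
      shapeSeparation = shapeSeparation,
      textureSeparation = textureSeparation, noiseSd = noiseSd,
      seed = as.integer(seed))
}
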