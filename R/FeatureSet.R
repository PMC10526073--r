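#' Feature table with provenance tag
#'
#' A \linkS4class{SummarizedExperiment} holding one assay \code{"features"}
#' (rows = feature dimensions, columns = samples), with \code{label} and
#' \code{view} in the colData and the sample source ids as column names,
#' plus a provenance \code{tag}: one of \code{lbp}, \code{hog}, \code{deep},
#' \code{fused}.
#'
#' @slot tag character(1) provenance tag.
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @export
setClass("FeatureSet", contains = "SummarizedExperiment",
         representation(tag = "character"))

setValidity("FeatureSet", function(object) {
  if (!object@tag %in% c("lbp", "hog", "deep", "fused"))
    return("tag must be one of lbp, hog, deep, fused")
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    return("assay 'features' is required")
  v <- SummarizedExperiment::assay(object, "features")
  if (nrow(v) < 1L) return("feature length must be > 0")
  if (!all(is.finite(v))) return("feature values must be finite")
  if (is.null(colnames(object))) return("column names (source ids) required")
  TRUE
})

#' Construct a FeatureSet
#'
#' @param values numeric matrix, feature dimensions x samples.
#' @param tag provenance tag (\code{lbp}, \code{hog}, \code{deep},
#'   \code{fused}).
#' @param sourceIds character, one id per sample (column names).
#' @param labels character, class label per sample.
#' @param views character, view per sample (recycled).
#' @return A \linkS4class{FeatureSet}.
#' @examples
#' fs <- FeatureSet(matrix(1:6, 3), "lbp", c("a", "b"), c("x", "y"))
#' featureTag(fs)
#' @importFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors DataFrame
#' @export
FeatureSet <- function(values, tag, sourceIds, labels,
                       views = rep("upper", length(sourceIds))) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  colnames(values) <- sourceIds
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = values),
    colData = S4Vectors::DataFrame(label = as.character(labels),
                                   view = rep(views, length.out = length(sourceIds)),
                                   row.names = sourceIds))
  new("FeatureSet", se, tag = tag)
}

#' @rdname FeatureSet
#' @param object,x a FeatureSet.
#' @export
setGeneric("featureTag", function(object) standardGeneric("featureTag"))

#' @rdname FeatureSet
#' @export
setMethod("featureTag", "FeatureSet", function(object) object@tag)

#' @rdname FeatureSet
#' @export
featureValues <- function(x) SummarizedExperiment::assay(x, "features")

#' @rdname FeatureSet
#' @export
featureLabels <- function(x) SummarizedExperiment::colData(x)$label

setMethod("show", "FeatureSet", function(object) {
  cat(sprintf("FeatureSet '%s': %d dimensions x %d samples (%d classes)\n",
              object@tag, nrow(object), ncol(object),
              length(unique(featureLabels(object)))))
})

#' Vector-stacking feature fusion
#'
#' Concatenates two feature vectors (or the per-sample columns of two
#' \linkS4class{FeatureSet}s) in the given order, producing a fused vector
#' whose length is exactly the sum of the input lengths. Inputs must refer
#' to the same samples: source ids are matched positionally and any
#' mismatch is an error.
#'
#' @param a,b \linkS4class{FeatureSet}s over identical source ids, or bare
#'   numeric vectors (in which case \code{sourceId} attributes, when
#'   present, must agree).
#' @return a fused \linkS4class{FeatureSet} (or numeric vector).
#' @examples
#' f1 <- FeatureSet(matrix(1:2, 1), "lbp", c("a", "b"), c("x", "y"))
#' f2 <- FeatureSet(matrix(3:6, 2), "deep", c("a", "b"), c("x", "y"))
#' dim(fuseFeatures(f1, f2))
#' @export
fuseFeatures <- function(a, b) {
  if (is.numeric(a) && is.numeric(b)) {
    ia <- attr(a, "sourceId"); ib <- attr(b, "sourceId")
    if (!is.null(ia) && !is.null(ib) && !identical(ia, ib))
      stop("cannot fuse features from different sources: ", ia, " vs ", ib)
    out <- c(as.numeric(a), as.numeric(b))
    attr(out, "sourceId") <- ia
    return(out)
  }
  stopifnot(is(a, "FeatureSet"), is(b, "FeatureSet"))
  if (!identical(colnames(a), colnames(b)))
    stop("cannot fuse feature sets: source ids differ")
  if (!identical(featureLabels(a), featureLabels(b)))
    stop("cannot fuse feature sets: labels differ")
  FeatureSet(rbind(featureValues(a), featureValues(b)), "fused",
             colnames(a), featureLabels(a),
             SummarizedExperiment::colData(a)$view)
}

#' Read/write feature tables as CSV
#'
#' One row per sample: \code{source_id, label, view, v1...vD}.
#'
#' @param x a FeatureSet; \code{path} a file path; \code{tag} the
#'   provenance tag to attach on read.
#' @param path,tag see above.
#' @return \code{readFeatureCSV} returns a \linkS4class{FeatureSet};
#'   \code{writeFeatureCSV} returns \code{path} invisibly.
#' @export
writeFeatureCSV <- function(x, path) {
  v <- t(featureValues(x))
  df <- data.frame(source_id = colnames(x), label = featureLabels(x),
                   view = SummarizedExperiment::colData(x)$view,
                   v, check.names = FALSE)
  colnames(df)[-(1:3)] <- paste0("v", seq_len(ncol(v)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureCSV
#' @export
readFeatureCSV <- function(path, tag) {
  df <- utils::read.csv(path, check.names = FALSE)
  FeatureSet(t(as.matrix(df[, -(1:3), drop = FALSE])), tag,
             as.character(df$source_id), as.character(df$label),
             as.character(df$view))
}
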