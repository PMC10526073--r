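#' Fit a one-vs-rest RBF SVM
#'
#' Trains K binary radial-basis-kernel maximum-margin machines (one per
#' class against the rest, K = number of classes) on the feature matrix.
#' When \code{standardize} is on, per-dimension location and scale are
#' computed on the training data only and reapplied at prediction time.
#' \code{gamma = NA} selects 1/(d * Var(X)) computed on the
#' (standardized) training matrix. The quadratic program is solved by
#' libsvm (via e1071); each machine's decision values are
#' orientation-checked so that positive always favors its class.
#'
#' @param features samples x dimensions numeric matrix, or a
#'   \linkS4class{FeatureSet} (samples = columns).
#' @param labels class label per sample (ignored for a FeatureSet).
#' @param config an \linkS4class{SVMConfig}.
#' @param seed integer RNG seed.
#' @return a \linkS4class{BeakClassifier}.
#' @examples
#' x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 6), 20))
#' clf <- fitClassifier(x, rep(c("a", "b"), each = 20), SVMConfig(), 1)
#' mean(predictLabels(clf, x) == rep(c("a", "b"), each = 20))
#' @export
fitClassifier <- function(features, labels = NULL, config = SVMConfig(),
                          seed = 1L) {
  validObject(config)
  tag <- "fused"
  if (is(features, "FeatureSet")) {
    labels <- featureLabels(features)
    tag <- featureTag(features)
    features <- t(featureValues(features))
  }
  x <- as.matrix(features)
  labels <- as.character(labels)
  if (nrow(x) != length(labels)) stop("features/labels length mismatch")
  if (!all(is.finite(x))) stop("non-finite feature values")
  classOrder <- sort(unique(labels))
  if (length(classOrder) < 2L)
    stop("need at least 2 classes; got ", length(classOrder))
  if (config@standardize) {
    ctr <- colMeans(x)
    scl <- apply(x, 2L, sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
  } else {
    ctr <- numeric(ncol(x)); scl <- rep(1, ncol(x))
  }
  xs <- sweep(sweep(x, 2L, ctr, "-"), 2L, scl, "/")
  gamma <- if (is.na(config@gamma)) {
    v <- mean(apply(xs, 2L, var))
    if (!is.finite(v) || v <= 0) v <- 1
    1 / (ncol(xs) * v)
  } else config@gamma
  set.seed(seed)
  machines <- vector("list", length(classOrder))
  signs <- numeric(length(classOrder))
  for (k in seq_along(classOrder)) {
    yk <- factor(ifelse(labels == classOrder[k], "pos", "rest"),
                 levels = c("pos", "rest"))
    fit <- e1071::svm(xs, yk, kernel = "radial", cost = config@cost,
                      gamma = gamma, scale = FALSE)
    dv <- attr(stats::predict(fit, xs, decision.values = TRUE),
               "decision.values")[, 1]
    # orient so positive decision value favors class k
    signs[k] <- if (mean(dv[labels == classOrder[k]]) >=
                    mean(dv[labels != classOrder[k]])) 1 else -1
    machines[[k]] <- fit
  }
  new("BeakClassifier", machines = machines, signs = signs,
      classOrder = classOrder, center = ctr, scale = scl, gamma = gamma,
      config = config, featureDim = ncol(x), tag = tag)
}

#' Predict class labels
#'
#' Applies the training standardization, evaluates each one-vs-rest
#' machine's decision value and predicts the argmax; exact ties are broken
#' by the fixed (sorted) class order. Outputs always belong to the
#' training label set.
#'
#' @param clf a \linkS4class{BeakClassifier}.
#' @param features samples x dimensions matrix or \linkS4class{FeatureSet};
#'   the dimension must match training.
#' @return character vector of predicted labels.
#' @export
predictLabels <- function(clf, features) {
  if (is(features, "FeatureSet")) features <- t(featureValues(features))
  x <- as.matrix(features)
  if (nrow(x) == 0L) return(character(0))
  if (ncol(x) != clf@featureDim)
    stop("feature length ", ncol(x), " does not match training (",
         clf@featureDim, ")")
  xs <- sweep(sweep(x, 2L, clf@center, "-"), 2L, clf@scale, "/")
  D <- vapply(seq_along(clf@machines), function(k) {
    dv <- attr(stats::predict(clf@machines[[k]], xs,
                              decision.values = TRUE),
               "decision.values")[, 1]
    clf@signs[k] * dv
  }, numeric(nrow(xs)))
  D <- matrix(D, nrow = nrow(xs))
  clf@classOrder[max.col(D, ties.method = "first")]
}

#' Persist / restore a trained classifier
#'
#' The model is written next to a version-stamped metadata JSON recording
#' the feature tag, dimension and configuration; \code{readClassifier}
#' refuses to load a model whose metadata does not match the requested
#' feature tag/dimension, so stale models cannot be applied to mismatched
#' features.
#'
#' @param clf a \linkS4class{BeakClassifier}; \code{path} an \code{.rds}
#'   path (metadata goes to \code{<path>.json}).
#' @param path file path.
#' @param expectTag,expectDim optional consistency checks on load.
#' @export
writeClassifier <- function(clf, path) {
  saveRDS(clf, path)
  meta <- list(package = "BeakFusion",
               version = as.character(utils::packageVersion("BeakFusion")),
               tag = clf@tag, featureDim = clf@featureDim,
               classes = clf@classOrder,
               C = clf@config@cost, gamma = clf@gamma, kernel = "rbf",
               decomposition = "one-vs-rest")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeClassifier
#' @export
readClassifier <- function(path, expectTag = NULL, expectDim = NULL) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!is.null(expectTag) && !identical(meta$tag, expectTag))
    stop("classifier was trained on '", meta$tag, "' features, not '",
         expectTag, "'")
  if (!is.null(expectDim) && meta$featureDim != expectDim)
    stop("classifier feature dimension ", meta$featureDim,
         " does not match ", expectDim)
  readRDS(path)
}
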