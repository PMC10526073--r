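#' Confusion matrix from predictions
#'
#' counts[i, j] = number of samples whose true class is classOrder[i] and
#' predicted class is classOrder[j].
#'
#' @param yTrue,yPred character vectors of equal length; every label must
#'   belong to \code{classOrder}.
#' @param classOrder label order; defaults to the sorted union of the
#'   observed labels.
#' @return a \linkS4class{ConfusionMatrix}.
#' @examples
#' confusionMatrix(c("A", "A", "B"), c("A", "B", "B"), c("A", "B"))
#' @export
confusionMatrix <- function(yTrue, yPred,
                            classOrder = sort(unique(c(yTrue, yPred)))) {
  yTrue <- as.character(yTrue); yPred <- as.character(yPred)
  if (length(yTrue) != length(yPred))
    stop("yTrue and yPred differ in length")
  bad <- setdiff(unique(c(yTrue, yPred)), classOrder)
  if (length(bad)) stop("labels outside classOrder: ",
                        paste(bad, collapse = ", "))
  k <- length(classOrder)
  counts <- matrix(0L, k, k, dimnames = list(true = classOrder,
                                             predicted = classOrder))
  if (length(yTrue)) {
    t <- table(factor(yTrue, classOrder), factor(yPred, classOrder))
    counts[] <- as.integer(t)
  }
  new("ConfusionMatrix", counts = counts, classOrder = classOrder)
}

#' Classification metrics from a confusion matrix
#'
#' Per class c (one-vs-rest): TP = counts[c, c], FP = column c minus TP,
#' FN = row c minus TP, TN = the rest, and
#' accuracy = (TP+TN)/(TP+TN+FP+FN), precision = TP/(TP+FP),
#' recall = TP/(TP+FN), F1 = 2PR/(P+R). Zero denominators yield 0 with a
#' warning. The aggregate row reports overall accuracy (trace/total) and
#' the macro (unweighted) mean of the per-class precision/recall/F1; on
#' balanced test sets macro and weighted averaging coincide. The
#' \code{perClass} accuracy column reports one-vs-rest recall, the
#' convention of per-species accuracy tables.
#'
#' @param cm a \linkS4class{ConfusionMatrix} with at least one count.
#' @return a \linkS4class{MetricsReport}.
#' @examples
#' cm <- confusionMatrix(rep(c("A", "B"), c(60, 40)),
#'                       rep(c("A", "B", "B", "A"), c(50, 10, 35, 5)),
#'                       c("A", "B"))
#' classMetrics(cm)
#' @export
classMetrics <- function(cm) {
  counts <- cm@counts
  total <- sum(counts)
  if (total == 0) stop("empty confusion matrix")
  k <- length(cm@classOrder)
  safe <- function(num, den, what, cl) {
    if (den == 0) {
      warning("zero denominator for ", what, " of class '", cl,
              "'; reporting 0", call. = FALSE)
      return(0)
    }
    num / den
  }
  per <- data.frame(class = cm@classOrder, accuracy = NA_real_,
                    precision = NA_real_, recall = NA_real_, f1 = NA_real_)
  for (i in seq_len(k)) {
    tp <- counts[i, i]
    fp <- sum(counts[, i]) - tp
    fn <- sum(counts[i, ]) - tp
    tn <- total - tp - fp - fn
    cl <- cm@classOrder[i]
    prec <- safe(tp, tp + fp, "precision", cl)
    rec <- safe(tp, tp + fn, "recall", cl)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    per$accuracy[i] <- rec  # per-class accuracy = one-vs-rest recall
    per$precision[i] <- prec
    per$recall[i] <- rec
    per$f1[i] <- f1
  }
  agg <- c(accuracy = sum(diag(counts)) / total,
           precision = mean(per$precision), recall = mean(per$recall),
           f1 = mean(per$f1))
  new("MetricsReport", perClass = per, aggregate = agg)
}

#' Write a metrics report as CSV
#'
#' One row per class plus an \code{ALL} aggregate row (overall accuracy and
#' macro precision/recall/F1), mirroring a per-species results table.
#'
#' @param report a \linkS4class{MetricsReport}; \code{path} a file path.
#' @param path output path.
#' @export
writeMetricsCSV <- function(report, path) {
  all <- data.frame(class = "ALL",
                    accuracy = report@aggregate["accuracy"],
                    precision = report@aggregate["precision"],
                    recall = report@aggregate["recall"],
                    f1 = report@aggregate["f1"])
  utils::write.csv(rbind(all, report@perClass), path, row.names = FALSE)
  invisible(path)
}

#' @rdname confusionMatrix
#' @param cm a \linkS4class{ConfusionMatrix}; \code{path} a file path.
#' @param path output path.
#' @export
writeConfusionCSV <- function(cm, path) {
  utils::write.csv(data.frame(true = cm@classOrder, cm@counts,
                              check.names = FALSE), path, row.names = FALSE)
  invisible(path)
}
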