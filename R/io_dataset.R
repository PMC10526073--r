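#' Load a labeled image from disk
#'
#' Decodes a PNG or JPEG file into a \linkS4class{BeakImage} with pixel
#' values in [0, 255] at the original resolution. The class label is taken
#' from the parent directory name and the view from the grandparent
#' directory when it is \code{upper} or \code{lower} (the
#' \code{root/<class>/<view>/image} layout); otherwise the view defaults
#' to \code{"upper"}.
#'
#' @param path path to a decodable \code{.png}, \code{.jpg} or \code{.jpeg}
#'   file.
#' @param label,view optional overrides for the inferred label and view.
#' @return a \linkS4class{BeakImage}.
#' @examples
#' img <- generateBeakDataset(SynthConfig(nPerClass = 1, views = "upper",
#'                                        imageSide = 64))[[1]]
#' d <- tempfile(); writeBeakDataset(list(img), d)
#' loadBeakImage(list.files(d, "\\.png$", recursive = TRUE,
#'                          full.names = TRUE)[1])
#' @export
loadBeakImage <- function(path, label = NULL, view = NULL) {
  if (!file.exists(path)) stop("image file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("png", "jpg", "jpeg"))
    stop("unsupported image format '", ext, "' for ", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("cannot decode image ", path, ": ",
                                           conditionMessage(e)))
  a <- EBImage::imageData(img)  # EBImage stores x (width) first
  d <- dim(a)
  if (length(d) == 2L) {
    p <- t(a) * 255
  } else {
    if (d[3] > 3L) a <- a[, , 1:3, drop = FALSE]  # drop alpha
    if (d[3] == 1L) p <- t(a[, , 1]) * 255
    else p <- aperm(a, c(2, 1, 3)) * 255
  }
  p <- clip01(p)
  dirs <- strsplit(normalizePath(path, mustWork = FALSE), "[/\\\\]")[[1]]
  n <- length(dirs)
  if (is.null(view))
    view <- if (n >= 3 && dirs[n - 1] %in% c("upper", "lower"))
      dirs[n - 1] else "upper"
  if (is.null(label))
    label <- if (n >= 3 && dirs[n - 1] %in% c("upper", "lower"))
      dirs[n - 2] else dirs[n - 1]
  BeakImage(p, label = label, view = view,
            sourceId = tools::file_path_sans_ext(basename(path)))
}

#' Grayscale conversion and bilinear resize
#'
#' Converts an image to grayscale with the fixed ITU-R 601 luminance
#' weighting 0.299 R + 0.587 G + 0.114 B and resizes it bilinearly (no
#' antialiasing) to \code{side} x \code{side}. Already-grayscale inputs of
#' the target size pass through unchanged.
#'
#' @param img a \linkS4class{BeakImage} or a pixel matrix/array in [0, 255].
#' @param side target side in pixels (>= 3). The LBP descriptor uses 512,
#'   HOG 256 and the reference backbone 224.
#' @return a numeric \code{side} x \code{side} matrix in [0, 255].
#' @examples
#' m <- toGrayResized(matrix(runif(100, 0, 255), 10), 5)
#' dim(m)
#' @export
toGrayResized <- function(img, side) {
  side <- as.integer(side)
  if (side < 3L) stop("side must be >= 3")
  p <- if (is(img, "BeakImage")) img@pixels else img
  g <- toLuminance(p)
  if (all(dim(g) == c(side, side))) return(g)
  bilinearResize(g, side, side)
}

#' Stratified train/validation/test split
#'
#' Splits a labeled id collection per class: a fraction \code{testFrac} of
#' each class goes to the test set and a fraction \code{valFracOfRest} of
#' the remainder to the validation set (the classifier-stage convention of
#' an 80/20 outer split whose 80% is again split 80/20 for network
#' training). Rounding keeps every per-class count within one sample of
#' the exact ratio, and the three sets are pairwise disjoint by
#' construction.
#'
#' @param idsByClass named list mapping class label to character ids, or a
#'   list of \linkS4class{BeakImage}s (grouped by their labels).
#' @param testFrac,valFracOfRest ratios in (0, 1).
#' @param seed integer; the split is deterministic given the seed.
#' @return a \linkS4class{DatasetSplit}.
#' @examples
#' s <- splitDataset(list(a = paste0("a", 1:10), b = paste0("b", 1:10)),
#'                   0.2, 0.2, seed = 1)
#' s
#' @export
splitDataset <- function(idsByClass, testFrac = 0.2, valFracOfRest = 0.2,
                         seed = 1L) {
  if (is.list(idsByClass) && length(idsByClass) &&
      is(idsByClass[[1]], "BeakImage")) {
    labs <- vapply(idsByClass, function(x) x@label, "")
    ids <- vapply(idsByClass, function(x) x@sourceId, "")
    idsByClass <- split(ids, labs)
  }
  if (testFrac <= 0 || testFrac >= 1 || valFracOfRest <= 0 ||
      valFracOfRest >= 1) stop("split fractions must be in (0, 1)")
  allIds <- unlist(idsByClass, use.names = FALSE)
  if (anyDuplicated(allIds)) stop("duplicate source ids across classes")
  train <- val <- test <- character(0)
  set.seed(seed)
  for (cl in names(idsByClass)) {
    ids <- idsByClass[[cl]]
    n <- length(ids)
    if (n < 3L) stop("class '", cl, "' has only ", n,
                     " samples; at least 3 are required")
    ids <- sample(ids)
    nTest <- min(max(round(testFrac * n), 1L), n - 2L)
    nVal <- min(max(round(valFracOfRest * (n - nTest)), 1L), n - nTest - 1L)
    test <- c(test, ids[seq_len(nTest)])
    val <- c(val, ids[nTest + seq_len(nVal)])
    train <- c(train, ids[(nTest + nVal + 1L):n])
  }
  new("DatasetSplit", train = train, val = val, test = test)
}

#' Write / load a dataset directory
#'
#' \code{writeBeakDataset} writes images as 8-bit PNG into the layout
#' \code{root/<class>/<view>/<sourceId>.png} (pixels are rounded to
#' integers, so the round-trip through PNG is lossless for integer-valued
#' images). \code{loadBeakDataset} reads every PNG/JPEG under such a tree.
#'
#' @param images list of \linkS4class{BeakImage}s.
#' @param root dataset directory.
#' @return \code{writeBeakDataset}: the root invisibly;
#'   \code{loadBeakDataset}: a list of \linkS4class{BeakImage}s.
#' @export
writeBeakDataset <- function(images, root) {
  for (img in images) {
    d <- file.path(root, img@label, img@view)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    p <- round(img@pixels) / 255
    if (length(dim(p)) == 3L) p <- aperm(p, c(1, 2, 3))  # writePNG wants HxWxC
    png::writePNG(p, file.path(d, paste0(img@sourceId, ".png")))
  }
  invisible(root)
}

#' @rdname writeBeakDataset
#' @export
loadBeakDataset <- function(root) {
  files <- list.files(root, pattern = "\\.(png|jpg|jpeg)$", recursive = TRUE,
                      full.names = TRUE, ignore.case = TRUE)
  if (!length(files)) stop("no PNG/JPEG images under ", root)
  lapply(sort(files), loadBeakImage)
}

#' Split manifest JSON
#'
#' Serializes a \linkS4class{DatasetSplit} as
#' \code{{"train": [...], "val": [...], "test": [...]}}.
#'
#' @param split a \linkS4class{DatasetSplit}; \code{path} a file path.
#' @param path output/input path.
#' @return \code{readSplitJSON} returns a \linkS4class{DatasetSplit}.
#' @export
writeSplitJSON <- function(split, path) {
  jsonlite::write_json(list(train = split@train, val = split@val,
                            test = split@test), path)
  invisible(path)
}

#' @rdname writeSplitJSON
#' @export
readSplitJSON <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("DatasetSplit", train = as.character(x$train),
      val = as.character(x$val), test = as.character(x$test))
}
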