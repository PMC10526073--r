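# Backbone profiles, training loop and deep-feature extraction.

#' Desk-scale learning-rate schedule
#'
#' A three-step decaying schedule (0.02, 0.007, 0.002 over 40/30/30% of the
#' epochs) that trains the deskSmall profile stably from scratch in a few
#' epochs on small fixtures. The reference50 profile keeps the two-step
#' 1e-3 / 1e-4 schedule of \code{\link{BackboneConfig}} as its default.
#'
#' @param epochs total number of epochs.
#' @return a 3-column (from, to, rate) matrix.
#' @export
deskLrSchedule <- function(epochs) {
  e1 <- max(1L, round(0.4 * epochs))
  e2 <- max(e1 + 1L, round(0.7 * epochs))
  rbind(c(1, e1, 0.02),
        c(e1 + 1, e2, 0.007),
        c(e2 + 1, max(e2 + 1, epochs), 0.002))
}

# Bottleneck residual block: 1x1 -> 3x3 (stride) -> 1x1(*4), projection
# shortcut when the shape changes.
bottleneckBlock <- function(inC, midC, stride) {
  outC <- 4L * midC
  main <- nnSeq(
    nnConv(inC, midC, 1L, 1L, 0L), nnBN(midC), nnReLU(),
    nnConv(midC, midC, 3L, stride, 1L), nnBN(midC), nnReLU(),
    nnConv(midC, outC, 1L, 1L, 0L), nnBN(outC))
  shortcut <- if (stride != 1L || inC != outC)
    nnSeq(nnConv(inC, outC, 1L, stride, 0L), nnBN(outC)) else NULL
  nnRes(main, shortcut)
}

buildReference50 <- function(nClasses) {
  stages <- list(c(64L, 3L, 1L), c(128L, 4L, 2L), c(256L, 6L, 2L),
                 c(512L, 3L, 2L))
  layers <- list(nnConv(3L, 64L, 7L, 2L, 3L), nnBN(64L), nnReLU(),
                 nnMaxPool(3L, 2L, 1L))
  inC <- 64L
  for (s in stages) {
    midC <- s[1]; nBlk <- s[2]; stride <- s[3]
    for (b in seq_len(nBlk)) {
      layers <- c(layers, list(bottleneckBlock(inC, midC,
                                               if (b == 1L) stride else 1L)))
      inC <- 4L * midC
    }
  }
  layers <- c(layers, list(nnGAP()))
  list(trunk = do.call(nnSeq, layers), head = nnDense(2048L, nClasses),
       featureDim = 2048L, channels = 3L)
}

buildDeskSmall <- function(nClasses, pooledDim) {
  trunk <- nnSeq(
    nnConv(1L, 8L, 3L, 1L, 1L), nnBN(8L), nnReLU(),
    nnConv(8L, 16L, 3L, 2L, 1L), nnBN(16L), nnReLU(),
    nnRes(nnSeq(nnConv(16L, 16L, 3L, 1L, 1L), nnBN(16L), nnReLU(),
                nnConv(16L, 16L, 3L, 1L, 1L), nnBN(16L))),
    nnConv(16L, pooledDim, 3L, 2L, 1L), nnBN(pooledDim), nnReLU(),
    nnGAP())
  list(trunk = trunk, head = nnDense(pooledDim, nClasses),
       featureDim = as.integer(pooledDim), channels = 1L)
}

#' Build a convolutional backbone
#'
#' \code{"reference50"} is the 50-layer bottleneck residual network
#' (stages of 3, 4, 6 and 3 blocks; global average pooling yields the
#' 2048-dimensional penultimate feature feeding an n-class output layer).
#' \code{"deskSmall"} is a 5-convolution residual network with a
#' configurable pooled dimension for CPU-scale training. Weights are
#' He-initialized from \code{config@seed}, so identical seeds give
#' identical networks.
#'
#' @param config a \linkS4class{BackboneConfig}.
#' @return an untrained \linkS4class{BeakBackbone}.
#' @examples
#' bb <- buildBackbone(BackboneConfig("deskSmall", inputSide = 32,
#'                                    pooledDim = 16))
#' bb
#' @export
buildBackbone <- function(config) {
  validObject(config)
  set.seed(config@seed)
  net <- switch(config@profile,
                reference50 = buildReference50(config@nClasses),
                deskSmall = buildDeskSmall(config@nClasses, config@pooledDim))
  new("BeakBackbone", net = net, config = config,
      featureDim = net$featureDim, classOrder = character(0),
      trained = FALSE,
      history = data.frame(epoch = integer(0), trainLoss = numeric(0),
                           valLoss = numeric(0), valAcc = numeric(0),
                           lr = numeric(0)))
}

# Preprocess a list of BeakImages into a (side, side, channels, N) array:
# grayscale, bilinear resize, scale to [0,1], standardize with the fixed
# constants mean 0.5 / sd 0.25, replicate channels for RGB backbones.
backboneInput <- function(imgs, config, net) {
  side <- config@inputSide
  N <- length(imgs)
  x <- array(0, c(side, side, net$channels, N))
  for (i in seq_len(N)) {
    g <- (toGrayResized(imgs[[i]], side) / 255 - 0.5) / 0.25
    for (ch in seq_len(net$channels)) x[, , ch, i] <- g
  }
  x
}

lrAtEpoch <- function(schedule, epoch) {
  for (r in seq_len(nrow(schedule)))
    if (epoch >= schedule[r, 1] && epoch <= schedule[r, 2])
      return(schedule[r, 3])
  schedule[nrow(schedule), 3]
}

backboneLogits <- function(net, x, train = FALSE) {
  rt <- nnForward(net$trunk, x, train)
  rh <- nnForward(net$head, rt$y, train)
  list(trunk = rt$m, head = rh$m, feats = rt$y, logits = rh$y)
}

#' Train a backbone by SGD with momentum
#'
#' Cross-entropy training on the training images with the configured
#' learning-rate schedule (default 1e-3 for epochs 1-50, 1e-4 for 51-100,
#' batch size 16); per-epoch training loss, validation loss and validation
#' accuracy are recorded and the weights achieving the best validation
#' loss are retained.
#'
#' @param backbone an untrained (or previously trained)
#'   \linkS4class{BeakBackbone}.
#' @param train,val disjoint lists of \linkS4class{BeakImage}s; their
#'   labels must cover exactly \code{nClasses} classes.
#' @param epochs optional override of \code{config@epochs}.
#' @param seed RNG seed for batch shuffling.
#' @return the trained \linkS4class{BeakBackbone} with its loss history.
#' @export
trainBackbone <- function(backbone, train, val, epochs = NULL, seed = 1L) {
  config <- backbone@config
  if (!length(train) || !length(val)) stop("empty train or validation set")
  if (length(intersect(vapply(train, function(x) x@sourceId, ""),
                       vapply(val, function(x) x@sourceId, ""))))
    stop("train and validation sets overlap")
  nEpochs <- if (is.null(epochs)) config@epochs else as.integer(epochs)
  if (nEpochs < 1L) stop("epochs must be >= 1")
  classOrder <- sort(unique(vapply(train, function(x) x@label, "")))
  if (length(classOrder) != config@nClasses)
    stop("training labels cover ", length(classOrder),
         " classes but nClasses = ", config@nClasses)
  net <- backbone@net
  xTr <- backboneInput(train, config, net)
  yTr <- match(vapply(train, function(x) x@label, ""), classOrder)
  xVal <- backboneInput(val, config, net)
  yVal <- match(vapply(val, function(x) x@label, ""), classOrder)
  if (anyNA(yVal)) stop("validation labels outside the training classes")
  N <- length(train)
  hist <- backbone@history
  best <- list(loss = Inf, trunk = NULL, head = NULL)
  set.seed(seed)
  for (ep in seq_len(nEpochs)) {
    lr <- lrAtEpoch(config@lrSchedule, ep)
    ord <- sample.int(N)
    batches <- split(ord, ceiling(seq_along(ord) / config@batchSize))
    epLoss <- 0
    for (bt in batches) {
      xb <- xTr[, , , bt, drop = FALSE]
      fw <- backboneLogits(net, xb, train = TRUE)
      sm <- nnSoftmaxXent(fw$logits, yTr[bt])
      epLoss <- epLoss + sm$loss * length(bt)
      bh <- nnBackward(fw$head, sm$dlogits)
      bt_ <- nnBackward(fw$trunk, bh$dx)
      net$trunk <- nnStep(bt_$m, lr, config@momentum)
      net$head <- nnStep(bh$m, lr, config@momentum)
    }
    ev <- backboneEval(net, xVal, yVal, config@batchSize)
    hist <- rbind(hist, data.frame(epoch = ep, trainLoss = epLoss / N,
                                   valLoss = ev$loss, valAcc = ev$acc,
                                   lr = lr))
    if (ev$loss < best$loss)
      best <- list(loss = ev$loss, trunk = nnStrip(net$trunk),
                   head = nnStrip(net$head))
  }
  if (!is.null(best$trunk)) { net$trunk <- best$trunk; net$head <- best$head }
  out <- backbone
  out@net <- net
  out@classOrder <- classOrder
  out@trained <- TRUE
  out@history <- hist
  out
}

backboneEval <- function(net, x, yIdx, batchSize) {
  N <- dim(x)[4]
  loss <- 0; correct <- 0
  for (bt in split(seq_len(N), ceiling(seq_len(N) / batchSize))) {
    fw <- backboneLogits(net, x[, , , bt, drop = FALSE], train = FALSE)
    sm <- nnSoftmaxXent(fw$logits, yIdx[bt])
    loss <- loss + sm$loss * length(bt)
    correct <- correct + sum(max.col(t(fw$logits), "first") == yIdx[bt])
  }
  list(loss = loss / N, acc = correct / N)
}

#' Extract deep features
#'
#' Runs the backbone in evaluation mode (batch-norm uses running
#' statistics, so features are independent of batch composition) and
#' returns the pooled penultimate activations -- the input of the final
#' fully connected layer; 2048-dimensional for the reference50 profile.
#'
#' @param backbone a \linkS4class{BeakBackbone} (an untrained backbone
#'   yields random-projection features).
#' @param imgs list of \linkS4class{BeakImage}s.
#' @return a \linkS4class{FeatureSet} with tag \code{"deep"}
#'   (featureDim x length(imgs)).
#' @export
extractDeep <- function(backbone, imgs) {
  config <- backbone@config
  net <- backbone@net
  N <- length(imgs)
  out <- matrix(0, backbone@featureDim, N)
  for (bt in split(seq_len(N), ceiling(seq_len(N) / config@batchSize))) {
    x <- backboneInput(imgs[bt], config, net)
    r <- nnForward(net$trunk, x, train = FALSE)
    out[, bt] <- r$y
  }
  FeatureSet(out, "deep",
             vapply(imgs, function(x) x@sourceId, ""),
             vapply(imgs, function(x) x@label, ""),
             vapply(imgs, function(x) x@view, ""))
}
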