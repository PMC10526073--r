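# Minimal convolutional-network framework: 4-D activations (H, W, C, N),
# convolution as im2col + BLAS matrix products, hand-written backward
# passes, and SGD with momentum. Modules are nested lists; forward/backward
# walk the tree functionally (caches live on the returned module copy).

nnIm2col <- function(x, kh, kw, stride, pad) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  if (pad > 0L) {
    xp <- array(0, c(H + 2L * pad, W + 2L * pad, C, N))
    xp[pad + seq_len(H), pad + seq_len(W), , ] <- x
    x <- xp; H <- H + 2L * pad; W <- W + 2L * pad
  }
  Ho <- (H - kh) %/% stride + 1L
  Wo <- (W - kw) %/% stride + 1L
  cols <- matrix(0, kh * kw * C, Ho * Wo * N)
  i <- 0L
  rs <- seq.int(1L, by = stride, length.out = Ho)
  cs <- seq.int(1L, by = stride, length.out = Wo)
  for (c in seq_len(C)) for (kj in seq_len(kw)) for (ki in seq_len(kh)) {
    i <- i + 1L
    cols[i, ] <- x[rs + (ki - 1L), cs + (kj - 1L), c, ]
  }
  list(cols = cols, Ho = Ho, Wo = Wo)
}

nnCol2im <- function(dcols, dimx, kh, kw, stride, pad, Ho, Wo) {
  H <- dimx[1] + 2L * pad; W <- dimx[2] + 2L * pad
  C <- dimx[3]; N <- dimx[4]
  dx <- array(0, c(H, W, C, N))
  i <- 0L
  rs <- seq.int(1L, by = stride, length.out = Ho)
  cs <- seq.int(1L, by = stride, length.out = Wo)
  for (c in seq_len(C)) for (kj in seq_len(kw)) for (ki in seq_len(kh)) {
    i <- i + 1L
    dx[rs + (ki - 1L), cs + (kj - 1L), c, ] <-
      dx[rs + (ki - 1L), cs + (kj - 1L), c, ] +
      array(dcols[i, ], c(Ho, Wo, N))
  }
  if (pad > 0L)
    dx <- dx[pad + seq_len(dimx[1]), pad + seq_len(dimx[2]), , , drop = FALSE]
  dx
}

# --- layer constructors (weights drawn from the current RNG state) -------

nnConv <- function(inC, outC, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  fanIn <- k * k * inC
  list(type = "conv", k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad), inC = inC, outC = outC,
       W = matrix(rnorm(fanIn * outC, sd = sqrt(2 / fanIn)), fanIn, outC),
       b = numeric(outC))
}

nnBN <- function(C, eps = 1e-5, mom = 0.1) {
  list(type = "bn", C = C, eps = eps, mom = mom,
       gamma = rep(1, C), beta = numeric(C),
       rmean = numeric(C), rvar = rep(1, C))
}

nnReLU <- function() list(type = "relu")
nnGAP <- function() list(type = "gap")
nnMaxPool <- function(k, stride, pad = 0L)
  list(type = "maxpool", k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad))

nnDense <- function(inD, outD) {
  list(type = "dense",
       W = matrix(rnorm(inD * outD, sd = sqrt(2 / inD)), inD, outD),
       b = numeric(outD))
}

nnSeq <- function(...) list(type = "seq", children = list(...))
nnRes <- function(main, shortcut = NULL)
  list(type = "res", main = main, shortcut = shortcut)

# --- forward --------------------------------------------------------------

nnForward <- function(m, x, train = FALSE) {
  switch(m$type,
    seq = {
      for (i in seq_along(m$children)) {
        r <- nnForward(m$children[[i]], x, train)
        if (train) m$children[[i]] <- r$m
        x <- r$y
      }
      list(m = m, y = x)
    },
    res = {
      rm_ <- nnForward(m$main, x, train)
      rs <- if (is.null(m$shortcut)) list(m = NULL, y = x)
            else nnForward(m$shortcut, x, train)
      s <- rm_$y + rs$y
      y <- pmax(s, 0)
      if (train) {
        m$main <- rm_$m
        if (!is.null(m$shortcut)) m$shortcut <- rs$m
        m$mask <- s > 0
      }
      list(m = m, y = y)
    },
    conv = {
      ic <- nnIm2col(x, m$k, m$k, m$stride, m$pad)
      out <- crossprod(ic$cols, m$W)           # (Ho*Wo*N) x outC
      out <- sweep(out, 2L, m$b, "+")
      N <- dim(x)[4]
      y <- aperm(array(out, c(ic$Ho, ic$Wo, N, m$outC)), c(1, 2, 4, 3))
      if (train) { m$cols <- ic$cols; m$dimx <- dim(x)
                   m$Ho <- ic$Ho; m$Wo <- ic$Wo }
      list(m = m, y = y)
    },
    bn = {
      d <- dim(x); nPer <- d[1] * d[2] * d[4]
      xm <- matrix(aperm(x, c(1, 2, 4, 3)), nPer, d[3])
      if (train) {
        mu <- colMeans(xm)
        v <- colMeans(xm^2) - mu^2
        m$rmean <- (1 - m$mom) * m$rmean + m$mom * mu
        m$rvar <- (1 - m$mom) * m$rvar + m$mom * v * nPer / max(nPer - 1, 1)
      } else {
        mu <- m$rmean; v <- m$rvar
      }
      istd <- 1 / sqrt(v + m$eps)
      xhat <- sweep(sweep(xm, 2L, mu, "-"), 2L, istd, "*")
      ym <- sweep(sweep(xhat, 2L, m$gamma, "*"), 2L, m$beta, "+")
      y <- aperm(array(ym, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
      if (train) { m$xhat <- xhat; m$istd <- istd; m$dimx <- d }
      list(m = m, y = y)
    },
    relu = {
      y <- pmax(x, 0)
      if (train) m$mask <- x > 0
      list(m = m, y = y)
    },
    maxpool = {
      d <- dim(x)
      if (m$pad > 0L) {
        xp <- array(-Inf, c(d[1] + 2L * m$pad, d[2] + 2L * m$pad, d[3], d[4]))
        xp[m$pad + seq_len(d[1]), m$pad + seq_len(d[2]), , ] <- x
      } else xp <- x
      dp <- dim(xp)
      Ho <- (dp[1] - m$k) %/% m$stride + 1L
      Wo <- (dp[2] - m$k) %/% m$stride + 1L
      rs <- seq.int(1L, by = m$stride, length.out = Ho)
      cs <- seq.int(1L, by = m$stride, length.out = Wo)
      y <- array(-Inf, c(Ho, Wo, d[3], d[4]))
      arg <- array(0L, c(Ho, Wo, d[3], d[4]))
      idx <- 0L
      for (kj in seq_len(m$k)) for (ki in seq_len(m$k)) {
        idx <- idx + 1L
        cand <- xp[rs + (ki - 1L), cs + (kj - 1L), , , drop = FALSE]
        upd <- cand > y
        y[upd] <- cand[upd]
        arg[upd] <- idx
      }
      if (train) { m$arg <- arg; m$dimx <- d; m$dimp <- dp
                   m$Ho <- Ho; m$Wo <- Wo }
      list(m = m, y = y)
    },
    gap = {
      d <- dim(x)
      y <- matrix(colMeans(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4])
      if (train) m$dimx <- d
      list(m = m, y = y)
    },
    dense = {
      y <- crossprod(m$W, x) + m$b   # x: (in, N) -> (out, N)
      if (train) m$x <- x
      list(m = m, y = y)
    },
    stop("unknown layer type ", m$type))
}

# --- backward (expects the module returned by a train-mode forward) -------

nnBackward <- function(m, dy) {
  switch(m$type,
    seq = {
      for (i in rev(seq_along(m$children))) {
        r <- nnBackward(m$children[[i]], dy)
        m$children[[i]] <- r$m
        dy <- r$dx
      }
      list(m = m, dx = dy)
    },
    res = {
      ds <- dy * m$mask
      rm_ <- nnBackward(m$main, ds)
      m$main <- rm_$m
      if (is.null(m$shortcut)) {
        dx <- rm_$dx + ds
      } else {
        rs <- nnBackward(m$shortcut, ds)
        m$shortcut <- rs$m
        dx <- rm_$dx + rs$dx
      }
      list(m = m, dx = dx)
    },
    conv = {
      N <- m$dimx[4]
      dmat <- matrix(aperm(dy, c(1, 2, 4, 3)), m$Ho * m$Wo * N, m$outC)
      m$gW <- m$cols %*% dmat
      m$gb <- colSums(dmat)
      dcols <- m$W %*% t(dmat)
      dx <- nnCol2im(dcols, m$dimx, m$k, m$k, m$stride, m$pad, m$Ho, m$Wo)
      m$cols <- NULL
      list(m = m, dx = dx)
    },
    bn = {
      d <- m$dimx; nPer <- d[1] * d[2] * d[4]
      dym <- matrix(aperm(dy, c(1, 2, 4, 3)), nPer, d[3])
      m$ggamma <- colSums(dym * m$xhat)
      m$gbeta <- colSums(dym)
      dxhat <- sweep(dym, 2L, m$gamma, "*")
      t1 <- sweep(dxhat, 2L, colMeans(dxhat), "-")
      t2 <- sweep(m$xhat, 2L, colMeans(dxhat * m$xhat), "*")
      dxm <- sweep(t1 - t2, 2L, m$istd, "*")
      dx <- aperm(array(dxm, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
      m$xhat <- NULL
      list(m = m, dx = dx)
    },
    relu = list(m = m, dx = dy * m$mask),
    maxpool = {
      dxp <- array(0, m$dimp)
      rs <- seq.int(1L, by = m$stride, length.out = m$Ho)
      cs <- seq.int(1L, by = m$stride, length.out = m$Wo)
      idx <- 0L
      for (kj in seq_len(m$k)) for (ki in seq_len(m$k)) {
        idx <- idx + 1L
        sel <- (m$arg == idx) * dy
        dxp[rs + (ki - 1L), cs + (kj - 1L), , ] <-
          dxp[rs + (ki - 1L), cs + (kj - 1L), , ] + sel
      }
      dx <- if (m$pad > 0L)
        dxp[m$pad + seq_len(m$dimx[1]), m$pad + seq_len(m$dimx[2]), , ,
            drop = FALSE]
      else dxp
      m$arg <- NULL
      list(m = m, dx = dx)
    },
    gap = {
      d <- m$dimx
      per <- 1 / (d[1] * d[2])
      dx <- array(rep(as.vector(dy) * per, each = d[1] * d[2]), d)
      list(m = m, dx = dx)
    },
    dense = {
      m$gW <- m$x %*% t(dy)
      m$gb <- rowSums(dy)
      dx <- m$W %*% dy
      m$x <- NULL
      list(m = m, dx = dx)
    },
    stop("unknown layer type ", m$type))
}

# --- SGD with momentum ----------------------------------------------------

nnStep <- function(m, lr, momentum) {
  upd <- function(m, pn, gn, vn) {
    if (is.null(m[[gn]])) return(m)
    v <- if (is.null(m[[vn]])) 0 else m[[vn]]
    v <- momentum * v + m[[gn]]
    m[[pn]] <- m[[pn]] - lr * v
    m[[vn]] <- v
    m[[gn]] <- NULL
    m
  }
  switch(m$type,
    seq = { m$children <- lapply(m$children, nnStep, lr, momentum); m },
    res = {
      m$main <- nnStep(m$main, lr, momentum)
      if (!is.null(m$shortcut)) m$shortcut <- nnStep(m$shortcut, lr, momentum)
      m
    },
    conv = upd(upd(m, "W", "gW", "vW"), "b", "gb", "vb"),
    dense = upd(upd(m, "W", "gW", "vW"), "b", "gb", "vb"),
    bn = upd(upd(m, "gamma", "ggamma", "vgamma"), "beta", "gbeta", "vbeta"),
    m)
}

# Strip caches/momentum so a snapshot holds parameters and running stats only.
nnStrip <- function(m) {
  keep <- c("type", "children", "main", "shortcut", "k", "stride", "pad",
            "inC", "outC", "C", "eps", "mom", "W", "b", "gamma", "beta",
            "rmean", "rvar")
  m <- m[intersect(names(m), keep)]
  if (m$type == "seq") m$children <- lapply(m$children, nnStrip)
  if (m$type == "res") {
    m$main <- nnStrip(m$main)
    if (!is.null(m$shortcut)) m$shortcut <- nnStrip(m$shortcut)
  }
  m
}

# Softmax cross-entropy over logits (K x N); yIdx in 1..K.
nnSoftmaxXent <- function(logits, yIdx) {
  K <- nrow(logits); N <- ncol(logits)
  z <- sweep(logits, 2L, apply(logits, 2L, max), "-")
  ez <- exp(z)
  p <- sweep(ez, 2L, colSums(ez), "/")
  picked <- p[cbind(yIdx, seq_len(N))]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dlog <- p
  dlog[cbind(yIdx, seq_len(N))] <- dlog[cbind(yIdx, seq_len(N))] - 1
  list(loss = loss, dlogits = dlog / N, prob = p)
}
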