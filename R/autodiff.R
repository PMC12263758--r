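## Minimal reverse-mode automatic differentiation for the 3D convolutional
## networks in this package. Feature maps are 4D arrays (x, y, z, channel);
## one sample per forward pass. Convolutions are BLAS-backed via im2col.
## This is deliberately a small, deterministic, single-threaded engine:
## everything the generator/discriminator need and nothing more.

adTape <- function() {
  e <- new.env(parent = emptyenv())
  e$ops <- list()
  e$n <- 0L
  e
}

adNode <- function(value, requiresGrad = FALSE) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$requiresGrad <- requiresGrad
  n
}

## internal op outputs always propagate gradient
.adOut <- function(value) adNode(value, requiresGrad = TRUE)

.adRecord <- function(tape, backward) {
  if (is.null(tape)) return(invisible(NULL))
  tape$n <- tape$n + 1L
  tape$ops[[tape$n]] <- backward
  invisible(NULL)
}

## wrap a backward so it no-ops when its output never received gradient
## (a recorded branch that does not reach the loss)

.adAccum <- function(node, g) {
  if (is.null(node)) return(invisible(NULL))
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

adBackward <- function(tape, loss) {
  loss$grad <- 1
  for (i in rev(seq_len(tape$n))) tape$ops[[i]]()
  invisible(NULL)
}

## ---- im2col machinery ------------------------------------------------

.colCache <- new.env(parent = emptyenv())

## column index matrix (positions x kernel*channels) into the zero-padded
## input, cached by geometry
.colIndex <- function(d, k, s, p) {
  key <- paste(c(d, k, s, p), collapse = "_")
  got <- .colCache[[key]]
  if (!is.null(got)) return(got)
  np <- d[1:3] + 2L * p
  o <- (np - k) %/% s + 1L
  px <- rep.int((seq_len(o[1]) - 1L) * s[1], o[2] * o[3])
  py <- rep.int(rep((seq_len(o[2]) - 1L) * s[2], each = o[1]), o[3])
  pz <- rep((seq_len(o[3]) - 1L) * s[3], each = o[1] * o[2])
  kk <- expand.grid(dx = 0:(k[1] - 1L), dy = 0:(k[2] - 1L),
                    dz = 0:(k[3] - 1L), c = 0:(d[4] - 1L))
  off <- kk$dx + np[1] * (kk$dy + np[2] * (kk$dz + np[3] * kk$c))
  base <- px + np[1] * (py + np[2] * pz)
  idx <- outer(base, off, "+") + 1L
  storage.mode(idx) <- "integer"
  idxVec <- idx
  dim(idxVec) <- NULL
  res <- list(idx = idx, idxVec = idxVec, npos = nrow(idx),
              outDim = o, padDim = c(np, d[4]))
  .colCache[[key]] <- res
  res
}

.pad4 <- function(x, p) {
  if (all(p == 0L)) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1:3] + 2L * p, d[4]))
  xp[p[1] + seq_len(d[1]), p[2] + seq_len(d[2]), p[3] + seq_len(d[3]), ] <- x
  xp
}

.unpad4 <- function(xp, p, d) {
  if (all(p == 0L)) return(xp)
  xp[p[1] + seq_len(d[1]), p[2] + seq_len(d[2]), p[3] + seq_len(d[3]), ,
     drop = FALSE]
}

## ---- operations ------------------------------------------------------

## 3D convolution; w: (kx, ky, kz, cin, cout) node, b: (cout) node
adConv3d <- function(tape, x, w, b, stride = c(1L, 1L, 1L),
                     padding = c(1L, 1L, 1L)) {
  d <- dim(x$value)
  k <- dim(w$value)[1:3]
  s <- as.integer(rep_len(stride, 3L)); p <- as.integer(rep_len(padding, 3L))
  ci <- dim(w$value)[4]; co <- dim(w$value)[5]
  if (d[4] != ci) .shapeError("conv3d: input has %d channels, weight expects %d",
                              d[4], ci)
  geom <- .colIndex(c(d[1:3], ci), k, s, p)
  xp <- .pad4(x$value, p)
  col <- xp[geom$idxVec]
  dim(col) <- c(geom$npos, length(col) %/% geom$npos)
  W2 <- matrix(w$value, ncol = co)
  outMat <- col %*% W2 + rep(b$value, each = geom$npos)
  dim(outMat) <- c(geom$outDim, co)
  out <- .adOut(outMat)
  .adRecord(tape, function() {
    if (is.null(out$grad)) return(invisible(NULL))
    doutMat <- out$grad
    dim(doutMat) <- c(geom$npos, co)
    .adAccum(w, array(crossprod(col, doutMat), dim(w$value)))
    .adAccum(b, colSums(doutMat))
    if (x$requiresGrad) {
      dcol <- doutMat %*% t(W2)
      dxp <- numeric(prod(geom$padDim))
      # for a fixed kernel offset the target positions are distinct, so
      # scatter-add is collision-free column by column
      for (j in seq_len(ncol(geom$idx))) {
        ii <- geom$idx[, j]
        dxp[ii] <- dxp[ii] + dcol[, j]
      }
      dim(dxp) <- geom$padDim
      .adAccum(x, .unpad4(dxp, p, d))
    }
  })
  out
}

adRelu <- function(tape, x) {
  out <- .adOut(pmax(x$value, 0))
  .adRecord(tape, function() if (!is.null(out$grad))
    .adAccum(x, out$grad * (x$value > 0)))
  out
}

adLeakyRelu <- function(tape, x, slope = 0.2) {
  fac <- (x$value > 0) * (1 - slope) + slope
  out <- .adOut(x$value * fac)
  .adRecord(tape, function() if (!is.null(out$grad))
    .adAccum(x, out$grad * fac))
  out
}

adSigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-x$value))
  out <- .adOut(s)
  .adRecord(tape, function() if (!is.null(out$grad))
    .adAccum(x, out$grad * s * (1 - s)))
  out
}

adAdd <- function(tape, a, b) {
  out <- .adOut(a$value + b$value)
  .adRecord(tape, function() {
    if (is.null(out$grad)) return(invisible(NULL))
    .adAccum(a, out$grad)
    .adAccum(b, out$grad)
  })
  out
}

## multiply feature map x (.., C) by a single-channel gate (.., 1)
adGateMul <- function(tape, x, gate) {
  d <- dim(x$value)
  grep <- array(gate$value, d)        # recycle the single channel
  out <- .adOut(x$value * grep)
  .adRecord(tape, function() {
    if (is.null(out$grad)) return(invisible(NULL))
    .adAccum(x, out$grad * grep)
    dg <- out$grad * x$value
    .adAccum(gate, array(rowSums(matrix(dg, ncol = d[4])), dim(gate$value)))
  })
  out
}

adConcat <- function(tape, a, b) {
  da <- dim(a$value); db <- dim(b$value)
  if (!identical(da[1:3], db[1:3]))
    .shapeError("concat: spatial shapes differ")
  out <- .adOut(array(c(a$value, b$value), c(da[1:3], da[4] + db[4])))
  .adRecord(tape, function() {
    if (is.null(out$grad)) return(invisible(NULL))
    g <- out$grad
    .adAccum(a, array(g[, , , seq_len(da[4]), drop = FALSE], da))
    .adAccum(b, array(g[, , , da[4] + seq_len(db[4]), drop = FALSE], db))
  })
  out
}

## 2x max pooling on every spatial axis (extents must be even)
adMaxPool2 <- function(tape, x) {
  d <- dim(x$value)
  if (any(d[1:3] %% 2L != 0L))
    .shapeError("maxpool: spatial extents must be even, got %s",
                paste(d[1:3], collapse = "x"))
  m <- d[1:3] %/% 2L
  subIdx <- function(a, b, cc) list(seq(1L + a, d[1], 2L),
                                    seq(1L + b, d[2], 2L),
                                    seq(1L + cc, d[3], 2L))
  offs <- expand.grid(a = 0:1, b = 0:1, cc = 0:1)
  best <- NULL; arg <- NULL
  for (j in seq_len(8)) {
    ii <- subIdx(offs$a[j], offs$b[j], offs$cc[j])
    cand <- x$value[ii[[1]], ii[[2]], ii[[3]], , drop = FALSE]
    if (j == 1) { best <- cand; arg <- array(1L, dim(cand)) }
    else {
      upd <- cand > best
      best[upd] <- cand[upd]
      arg[upd] <- j
    }
  }
  out <- .adOut(best)
  .adRecord(tape, function() {
    if (is.null(out$grad)) return(invisible(NULL))
    dx <- array(0, d)
    for (j in seq_len(8)) {
      ii <- subIdx(offs$a[j], offs$b[j], offs$cc[j])
      g <- out$grad * (arg == j)
      dx[ii[[1]], ii[[2]], ii[[3]], ] <-
        dx[ii[[1]], ii[[2]], ii[[3]], , drop = FALSE] + g
    }
    .adAccum(x, dx)
  })
  out
}

## nearest-neighbour 2x upsampling on every spatial axis
adUpsample2 <- function(tape, x) {
  d <- dim(x$value)
  rx <- rep(seq_len(d[1]), each = 2L)
  ry <- rep(seq_len(d[2]), each = 2L)
  rz <- rep(seq_len(d[3]), each = 2L)
  out <- .adOut(x$value[rx, ry, rz, , drop = FALSE])
  .adRecord(tape, function() {
    if (is.null(out$grad)) return(invisible(NULL))
    g <- out$grad
    acc <- array(0, d)
    for (a in 0:1) for (b in 0:1) for (cc in 0:1)
      acc <- acc + g[seq(1L + a, 2L * d[1], 2L), seq(1L + b, 2L * d[2], 2L),
                     seq(1L + cc, 2L * d[3], 2L), , drop = FALSE]
    .adAccum(x, acc)
  })
  out
}

## mean |x - target| over all elements; target is a plain array
adL1Loss <- function(tape, x, target) {
  diff <- x$value - target
  out <- .adOut(mean(abs(diff)))
  .adRecord(tape, function() if (!is.null(out$grad))
    .adAccum(x, out$grad * sign(diff) / length(diff)))
  out
}

## mean binary cross-entropy of logits against a constant label (0 or 1)
adBCEWithLogits <- function(tape, logits, label) {
  z <- logits$value
  out <- .adOut(mean(pmax(z, 0) - z * label + log1p(exp(-abs(z)))))
  .adRecord(tape, function() {
    if (is.null(out$grad)) return(invisible(NULL))
    s <- 1 / (1 + exp(-z))
    .adAccum(logits, out$grad * (s - label) / length(z))
  })
  out
}

## weighted sum of two scalar nodes
adAxpy <- function(tape, wa, a, wb, b) {
  out <- .adOut(wa * a$value + wb * b$value)
  .adRecord(tape, function() {
    if (is.null(out$grad)) return(invisible(NULL))
    .adAccum(a, out$grad * wa)
    .adAccum(b, out$grad * wb)
  })
  out
}

## ---- parameters and optimizer ---------------------------------------

## He-uniform initialization for a conv weight of the given shape
.initConvW <- function(shape) {
  fanIn <- prod(shape[1:4])
  lim <- sqrt(6 / fanIn)
  array(runif(prod(shape), -lim, lim), shape)
}

## wrap a named list of arrays as gradient-carrying nodes
.paramNodes <- function(params)
  lapply(params, adNode, requiresGrad = TRUE)

.paramValues <- function(nodes) lapply(nodes, function(n) n$value)

.zeroGrads <- function(nodes)
  invisible(lapply(nodes, function(n) n$grad <- NULL))

adamState <- function(params)
  list(m = lapply(params, function(p) array(0, dim(p))),
       v = lapply(params, function(p) array(0, dim(p))),
       t = 0L)

## one Adam update over node list; returns updated state (nodes updated
## in place); grads of NULL are treated as zero
adamStep <- function(nodes, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(nodes)) {
    g <- nodes[[nm]]$grad
    if (is.null(g)) g <- 0
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    nodes[[nm]]$value <- nodes[[nm]]$value -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  state
}
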