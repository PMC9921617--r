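# Batched bidirectional LSTM engine.
#
# Sequences are stored as an array (N, T, D); each time step is processed
# as an N x D matrix so all heavy lifting is BLAS matrix products. Gate
# layout in the packed 4H dimension: input, forget, candidate, output.

sigmoid <- function(x) 1 / (1 + exp(-x))

# Glorot-uniform LSTM weights; zero-initialised readout so that the
# decision direction is purely learned even under a conservative learning
# rate (the softmax argmax is scale-free, so small coherent readout
# updates dominate from the start)
lstmInit <- function(inputDim, hidden, nClasses, seed) {
  withSeed(seed, {
    gu <- function(nr, nc) {
      r <- sqrt(6 / (nr + nc))
      matrix(stats::runif(nr * nc, -r, r), nr, nc)
    }
    mkDir <- function() {
      b <- rep(0, 4 * hidden)
      b[hidden + seq_len(hidden)] <- 1 # forget-gate bias
      list(Wx = gu(inputDim, 4 * hidden), Wh = gu(hidden, 4 * hidden), b = b)
    }
    list(
      fwd = mkDir(), bwd = mkDir(),
      Wy = matrix(0, 2 * hidden, nClasses), by = rep(0, nClasses)
    )
  })
}

# forward pass of one direction over time order `ord`; returns the final
# hidden state and the per-step cache needed for backpropagation
lstmForwardDir <- function(x, idx, ord, par, hidden) {
  n <- length(idx)
  h <- matrix(0, n, hidden)
  cc <- matrix(0, n, hidden)
  cache <- vector("list", length(ord))
  gi <- seq_len(hidden)
  for (k in seq_along(ord)) {
    t <- ord[k]
    xt <- x[idx, t, , drop = FALSE]
    dim(xt) <- c(n, dim(x)[3])
    a <- xt %*% par$Wx + h %*% par$Wh
    a <- sweep(a, 2, par$b, "+")
    ig <- sigmoid(a[, gi, drop = FALSE])
    fg <- sigmoid(a[, hidden + gi, drop = FALSE])
    gg <- tanh(a[, 2 * hidden + gi, drop = FALSE])
    og <- sigmoid(a[, 3 * hidden + gi, drop = FALSE])
    cPrev <- cc
    cc <- fg * cPrev + ig * gg
    hPrev <- h
    h <- og * tanh(cc)
    cache[[k]] <- list(t = t, xt = xt, i = ig, f = fg, g = gg, o = og,
                       c = cc, cPrev = cPrev, hPrev = hPrev)
  }
  list(h = h, cache = cache)
}

# backpropagation through time for one direction given the gradient at the
# final hidden state; returns parameter gradients
lstmBackwardDir <- function(dhFinal, cache, par, hidden) {
  dWx <- matrix(0, nrow(par$Wx), ncol(par$Wx))
  dWh <- matrix(0, hidden, 4 * hidden)
  db <- rep(0, 4 * hidden)
  dh <- dhFinal
  dc <- matrix(0, nrow(dhFinal), hidden)
  for (k in rev(seq_along(cache))) {
    st <- cache[[k]]
    tc <- tanh(st$c)
    do <- dh * tc
    dc <- dc + dh * st$o * (1 - tc^2)
    di <- dc * st$g
    df <- dc * st$cPrev
    dg <- dc * st$i
    da <- cbind(
      di * st$i * (1 - st$i),
      df * st$f * (1 - st$f),
      dg * (1 - st$g^2),
      do * st$o * (1 - st$o)
    )
    dWx <- dWx + crossprod(st$xt, da)
    dWh <- dWh + crossprod(st$hPrev, da)
    db <- db + colSums(da)
    dh <- da %*% t(par$Wh)
    dc <- dc * st$f
  }
  list(Wx = dWx, Wh = dWh, b = db)
}

# forward through both directions + readout; training mode applies
# inverted dropout to the concatenated final hidden states
bilstmForward <- function(x, idx, params, hidden, dropout = 0,
                          dropMask = NULL) {
  tt <- dim(x)[2]
  fwd <- lstmForwardDir(x, idx, seq_len(tt), params$fwd, hidden)
  bwd <- lstmForwardDir(x, idx, rev(seq_len(tt)), params$bwd, hidden)
  z <- cbind(fwd$h, bwd$h)
  zd <- z
  if (dropout > 0 && !is.null(dropMask)) {
    zd <- z * dropMask / (1 - dropout)
  }
  logits <- sweep(zd %*% params$Wy, 2, params$by, "+")
  m <- apply(logits, 1, max)
  el <- exp(logits - m)
  probs <- el / rowSums(el)
  list(fwd = fwd, bwd = bwd, z = z, zd = zd, probs = probs)
}

# full backward pass: softmax cross-entropy + L2 on weight matrices
bilstmBackward <- function(fwdPass, yOneHot, params, hidden, l2,
                           dropout = 0, dropMask = NULL) {
  n <- nrow(yOneHot)
  dLogits <- (fwdPass$probs - yOneHot) / n
  dWy <- crossprod(fwdPass$zd, dLogits) + l2 * params$Wy
  dby <- colSums(dLogits)
  dzd <- tcrossprod(dLogits, params$Wy)
  dz <- dzd
  if (dropout > 0 && !is.null(dropMask)) {
    dz <- dzd * dropMask / (1 - dropout)
  }
  gi <- seq_len(hidden)
  gFwd <- lstmBackwardDir(dz[, gi, drop = FALSE], fwdPass$fwd$cache,
                          params$fwd, hidden)
  gBwd <- lstmBackwardDir(dz[, hidden + gi, drop = FALSE],
                          fwdPass$bwd$cache, params$bwd, hidden)
  gFwd$Wx <- gFwd$Wx + l2 * params$fwd$Wx
  gFwd$Wh <- gFwd$Wh + l2 * params$fwd$Wh
  gBwd$Wx <- gBwd$Wx + l2 * params$bwd$Wx
  gBwd$Wh <- gBwd$Wh + l2 * params$bwd$Wh
  list(fwd = gFwd, bwd = gBwd, Wy = dWy, by = dby)
}

# Adam update applied in place over the nested parameter list
adamInitState <- function(params) {
  rapply(params, function(p) p * 0, how = "replace")
}

adamStep <- function(params, grads, mState, vState, lr, step,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mHat <- m / (1 - beta1^step)
    vHat <- v / (1 - beta2^step)
    list(p = p - lr * mHat / (sqrt(vHat) + eps), m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      list(
        p = lapply(out, `[[`, "p"),
        m = lapply(out, `[[`, "m"),
        v = lapply(out, `[[`, "v")
      )
    } else {
      upd(p, g, m, v)
    }
  }
  walk(params, grads, mState, vState)
}

# cross-entropy (with L2 term) of one forward pass
bilstmLoss <- function(probs, yOneHot, params, l2) {
  ce <- -mean(log(pmax(rowSums(probs * yOneHot), 1e-12)))
  wts <- c(params$fwd[c("Wx", "Wh")], params$bwd[c("Wx", "Wh")],
           list(params$Wy))
  ce + 0.5 * l2 * sum(vapply(wts, function(w) sum(w^2), numeric(1)))
}

# train a bidirectional LSTM on an (N, T, D) array with integer labels
# 1..C; returns fitted parameters and the per-iteration training log
bilstmTrain <- function(x, y, hidden, config) {
  n <- dim(x)[1]
  d <- dim(x)[3]
  nc <- max(y)
  params <- lstmInit(d, hidden, nc, config@rngSeed)
  mState <- adamInitState(params)
  vState <- adamInitState(params)
  yOneHot <- diag(nc)[y, , drop = FALSE]
  log <- data.frame(iteration = integer(), learningRate = numeric(),
                    loss = numeric())
  step <- 0L
  withSeed(subSeed(config@rngSeed, 7L), {
    for (iter in seq_len(config@maxIterations)) {
      lr <- config@initialLearningRate * config@lrDecayFactor^(iter - 1L)
      perm <- sample.int(n)
      batches <- split(perm, ceiling(seq_along(perm) / config@batchSize))
      lossSum <- 0
      for (idx in batches) {
        mask <- NULL
        if (config@dropoutRate > 0) {
          mask <- matrix(
            stats::rbinom(length(idx) * 2 * hidden, 1,
                          1 - config@dropoutRate),
            length(idx), 2 * hidden
          )
        }
        fp <- bilstmForward(x, idx, params, hidden, config@dropoutRate, mask)
        yb <- yOneHot[idx, , drop = FALSE]
        lossSum <- lossSum + bilstmLoss(fp$probs, yb, params,
                                        config@l2Penalty) * length(idx)
        grads <- bilstmBackward(fp, yb, params, hidden, config@l2Penalty,
                                config@dropoutRate, mask)
        step <- step + 1L
        out <- adamStep(params, grads, mState, vState, lr, step)
        params <- out$p
        mState <- out$m
        vState <- out$v
      }
      log <- rbind(log, data.frame(
        iteration = iter, learningRate = lr, loss = lossSum / n
      ))
    }
  })
  list(params = params, log = log)
}

# inference: class probabilities for an (N, T, D) array
bilstmPredict <- function(x, params, hidden) {
  fp <- bilstmForward(x, seq_len(dim(x)[1]), params, hidden)
  fp$probs
}
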