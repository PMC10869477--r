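# Forward and backward passes of the classifier. The architecture is fixed,
# so backpropagation is written out explicitly layer by layer; correctness is
# pinned by finite-difference tests. All activations are column-major R
# arrays; the window axis is last.
#
# Internal layouts (logical Table-style shapes in comments):
#   input        (C, T, n)               -- (1, C, T) per window
#   conv1 out    (C, T, F1, n)           -- (F1, C, T)
#   depthwise    (M, T, n), M = F2*F1    -- (F2*F1, 1, T)
#   pooled1      (M, T1, n)              -- (F2*F1, 1, T/16)
#   conv3 out    (M, T1, F3, n)          -- (F3, F2*F1, T1)  [maps folded into
#                                           the spatial axis of a single map]
#   pooled2      (M, T2, F3, n)          -- (F3, F2*F1, T1/16)
#   features     (D, n), D = F3*M*T2

bn_eps <- 1e-5
bn_momentum <- 0.1

# --- batch norm over the 3rd axis of a (d1, d2, F, n) array -----------------

bn3_forward <- function(a, gamma, beta, train, rm, rv) {
  d <- dim(a)
  g <- d[3]
  blk <- d[1] * d[2]
  if (train) {
    cm <- .colMeans(a, blk, g * d[4])
    mu <- .rowMeans(cm, g, d[4])
    ex2 <- .rowMeans(.colMeans(a * a, blk, g * d[4]), g, d[4])
    v <- pmax(ex2 - mu^2, 0)
    rm <- (1 - bn_momentum) * rm + bn_momentum * mu
    rv <- (1 - bn_momentum) * rv + bn_momentum * v
  } else {
    mu <- rm
    v <- rv
  }
  isd <- 1 / sqrt(v + bn_eps)
  xhat <- (a - rep(mu, each = blk)) * rep(isd, each = blk)
  y <- xhat * rep(gamma, each = blk) + rep(beta, each = blk)
  list(y = y, xhat = xhat, isd = isd, rm = rm, rv = rv, train = train)
}

bn3_backward <- function(gy, cache, gamma) {
  d <- dim(gy)
  g <- d[3]
  blk <- d[1] * d[2]
  s1 <- .rowSums(.colSums(gy, blk, g * d[4]), g, d[4])
  s2 <- .rowSums(.colSums(gy * cache$xhat, blk, g * d[4]), g, d[4])
  gisd <- rep(gamma * cache$isd, each = blk)
  if (cache$train) {
    n_per <- blk * d[4]
    gx <- gisd * (gy - rep(s1 / n_per, each = blk) -
                    cache$xhat * rep(s2 / n_per, each = blk))
  } else {
    gx <- gisd * gy
  }
  list(gx = gx, ggamma = s2, gbeta = s1)
}

# --- batch norm over the 1st axis of a (M, T, n) array ----------------------

bn1_forward <- function(a, gamma, beta, train, rm, rv) {
  d <- dim(a)
  nc <- prod(d[-1])
  m <- a
  dim(m) <- c(d[1], nc)
  if (train) {
    mu <- .rowMeans(m, d[1], nc)
    v <- pmax(.rowMeans(m * m, d[1], nc) - mu^2, 0)
    rm <- (1 - bn_momentum) * rm + bn_momentum * mu
    rv <- (1 - bn_momentum) * rv + bn_momentum * v
  } else {
    mu <- rm
    v <- rv
  }
  isd <- 1 / sqrt(v + bn_eps)
  xhat <- (m - mu) * isd
  y <- xhat * gamma + beta
  dim(y) <- d
  dim(xhat) <- d
  list(y = y, xhat = xhat, isd = isd, rm = rm, rv = rv, train = train)
}

bn1_backward <- function(gy, cache, gamma) {
  d <- dim(gy)
  nc <- prod(d[-1])
  gm <- gy
  dim(gm) <- c(d[1], nc)
  xh <- cache$xhat
  dim(xh) <- c(d[1], nc)
  s1 <- .rowSums(gm, d[1], nc)
  s2 <- .rowSums(gm * xh, d[1], nc)
  if (cache$train) {
    n_per <- prod(d) / d[1]
    gx <- (gamma * cache$isd) * (gm - s1 / n_per - xh * (s2 / n_per))
  } else {
    gx <- (gamma * cache$isd) * gm
  }
  dim(gx) <- d
  list(gx = gx, ggamma = s2, gbeta = s1)
}

# --- average pooling along a time axis --------------------------------------

# a: array whose 2nd axis is time (3D or 4D). Pools by `pool`, averaging.
pool_time <- function(a, pool) {
  d <- dim(a)
  tb <- d[2] %/% pool
  rest <- prod(d[-(1:2)])
  dim(a) <- c(d[1], pool, tb * rest)
  y <- a[, 1, , drop = FALSE]
  for (j in 2:pool) y <- y + a[, j, , drop = FALSE]
  y <- y / pool
  dim(y) <- c(d[1], tb, d[-(1:2)])
  y
}

pool_time_backward <- function(gy, pool, orig_dim) {
  d <- dim(gy)
  rest <- prod(d[-1])
  g <- matrix(gy / pool, d[1])           # (d1, tb*rest)
  gfull <- aperm(array(g, c(d[1], rest, pool)), c(1, 3, 2))
  dim(gfull) <- orig_dim
  gfull
}

# --- dropout ----------------------------------------------------------------

dropout_forward <- function(a, p, train) {
  if (!train || p == 0) return(list(y = a, mask = NULL))
  mask <- (stats::runif(length(a)) >= p) / (1 - p)
  list(y = a * mask, mask = mask)
}

# --- softmax / cross-entropy ------------------------------------------------

softmax_cols <- function(z) {
  z <- z - rep(apply(z, 2, max), each = nrow(z))
  e <- exp(z)
  e / rep(colSums(e), each = nrow(z))
}

# mean cross-entropy over the batch; y is 0/1
cross_entropy <- function(probs, y) {
  n <- ncol(probs)
  p <- probs[cbind(y + 1L, seq_len(n))]
  -mean(log(pmax(p, 1e-12)))
}

cross_entropy_grad <- function(probs, y) {
  n <- ncol(probs)
  g <- probs
  g[cbind(y + 1L, seq_len(n))] <- g[cbind(y + 1L, seq_len(n))] - 1
  g / n
}

# --- full forward -----------------------------------------------------------

coerce_batch <- function(model, x) {
  if (inherits(x, "window_set")) x <- x$x
  assert_that(is.array(x) && length(dim(x)) == 3L,
              "batch must be a (C, T, n) array or a window_set")
  cfg <- model$config
  assert_that(dim(x)[1] == cfg$C && dim(x)[2] == cfg$T,
              sprintf("batch shape (%d, %d) does not match the model's expected (C = %d, T = %d)",
                      dim(x)[1], dim(x)[2], cfg$C, cfg$T))
  x
}

# Returns logits/probs/features plus every cache needed for the backward pass.
# In train mode, dropout consumes the current RNG stream and batch-norm uses
# batch statistics (running statistics are returned updated in `state`).
model_forward <- function(model, x, train = FALSE) {
  x <- coerce_batch(model, x)
  cfg <- model$config
  p <- model$params
  st <- model$state
  n <- dim(x)[3]
  M <- cfg$F1 * cfg$F2
  pad1 <- (cfg$kernel1 - 1L) %/% 2L
  pad2 <- (cfg$kernel2 - 1L) %/% 2L

  a1 <- cpp_tconv_forward(x, p$w1, cfg$C, cfg$T, n, pad1)        # (C,T,F1,n)
  b1 <- bn3_forward(a1, p$bn1_gamma, p$bn1_beta, train, st$bn1_rm, st$bn1_rv)
  a2 <- cpp_dwconv_forward(b1$y, p$wd, cfg$C, cfg$T, cfg$F1, cfg$F2, n) # (M,T,n)
  b2 <- bn1_forward(a2, p$bn2_gamma, p$bn2_beta, train, st$bn2_rm, st$bn2_rv)
  r1 <- pmax(b2$y, 0)
  pl1 <- pool_time(r1, cfg$pool)                                  # (M,T1,n)
  dr1 <- dropout_forward(pl1, cfg$dropout_p, train)
  t1 <- cfg$T %/% cfg$pool
  a3 <- cpp_tconv_forward(dr1$y, p$w3, M, t1, n, pad2)            # (M,T1,F3,n)
  b3 <- bn3_forward(a3, p$bn3_gamma, p$bn3_beta, train, st$bn3_rm, st$bn3_rv)
  r2 <- pmax(b3$y, 0)
  pl2 <- pool_time(r2, cfg$pool)                                  # (M,T2,F3,n)
  dr2 <- dropout_forward(pl2, cfg$dropout_p, train)
  feat <- matrix(dr2$y, embedding_dim(cfg), n)                    # (D,n)
  logits <- p$wfc %*% feat + p$bfc
  probs <- softmax_cols(logits)

  state <- list(bn1_rm = b1$rm, bn1_rv = b1$rv, bn2_rm = b2$rm,
                bn2_rv = b2$rv, bn3_rm = b3$rm, bn3_rv = b3$rv)
  list(features = feat, logits = logits, probs = probs, state = state,
       cache = list(x = x, a1 = a1, b1 = b1, a2 = a2, b2 = b2, r1 = r1,
                    pl1 = pl1, dr1 = dr1, a3 = a3, b3 = b3, r2 = r2,
                    pl2 = pl2, dr2 = dr2, n = n))
}

# Backward pass. `dlogits` is the gradient at the dense pre-softmax output;
# `dfeat_extra` (D x n or NULL) is any additional gradient injected at the
# feature embedding — this is where the (reversed) domain-discriminator
# gradient enters during adversarial training.
model_backward <- function(model, fwd, dlogits, dfeat_extra = NULL) {
  cfg <- model$config
  p <- model$params
  ch <- fwd$cache
  n <- ch$n
  M <- cfg$F1 * cfg$F2
  t1 <- cfg$T %/% cfg$pool
  t2 <- t1 %/% cfg$pool
  pad1 <- (cfg$kernel1 - 1L) %/% 2L
  pad2 <- (cfg$kernel2 - 1L) %/% 2L

  gwfc <- dlogits %*% t(fwd$features)
  gbfc <- rowSums(dlogits)
  gfeat <- t(p$wfc) %*% dlogits
  if (!is.null(dfeat_extra)) gfeat <- gfeat + dfeat_extra

  g <- array(gfeat, c(M, t2, cfg$F3, n))
  if (!is.null(ch$dr2$mask)) g <- g * ch$dr2$mask
  g <- pool_time_backward(g, cfg$pool, c(M, t1, cfg$F3, n))
  g <- g * (ch$b3$y > 0)
  bb3 <- bn3_backward(g, ch$b3, p$bn3_gamma)
  gw3 <- cpp_tconv_backward_w(ch$dr1$y, bb3$gx, M, t1, n, cfg$F3,
                              cfg$kernel2, pad2)
  g <- cpp_tconv_backward_x(bb3$gx, p$w3, M, t1, n, pad2)          # (M,T1,n)
  if (!is.null(ch$dr1$mask)) g <- g * ch$dr1$mask
  g <- pool_time_backward(g, cfg$pool, c(M, cfg$T, n))
  g <- g * (ch$b2$y > 0)
  bb2 <- bn1_backward(g, ch$b2, p$bn2_gamma)
  gwd <- cpp_dwconv_backward_w(ch$b1$y, bb2$gx, cfg$C, cfg$T, cfg$F1,
                               cfg$F2, n)
  g <- cpp_dwconv_backward_x(bb2$gx, p$wd, cfg$C, cfg$T, cfg$F1, cfg$F2, n)
  bb1 <- bn3_backward(g, ch$b1, p$bn1_gamma)
  gw1 <- cpp_tconv_backward_w(ch$x, bb1$gx, cfg$C, cfg$T, n, cfg$F1,
                              cfg$kernel1, pad1)

  list(w1 = gw1, bn1_gamma = bb1$ggamma, bn1_beta = bb1$gbeta,
       wd = gwd, bn2_gamma = bb2$ggamma, bn2_beta = bb2$gbeta,
       w3 = gw3, bn3_gamma = bb3$ggamma, bn3_beta = bb3$gbeta,
       wfc = gwfc, bfc = gbfc)
}

#' Run the classifier forward on a batch of windows
#'
#' Evaluation-mode forward pass: batch normalization uses running statistics
#' and dropout is inactive, so the output is deterministic and per-window
#' (no cross-example coupling).
#'
#' @param model A `seiz_model`.
#' @param batch A `(C, T, n)` array or a `window_set`.
#' @return A list with `features` (n x D matrix, the embedding phi(x)) and
#'   `probs` (n x 2 matrix of class probabilities, columns inter-ictal /
#'   pre-ictal).
#' @export
forward <- function(model, batch) {
  assert_that(inherits(model, "seiz_model"), "`model` must be a seiz_model")
  out <- model_forward(model, batch, train = FALSE)
  list(features = t(out$features), probs = t(out$probs))
}

#' Classify windows with a trained model
#'
#' @param model A `seiz_model`.
#' @param ws A `window_set` (or `(C, T, n)` array).
#' @param batch_size Forward-pass batch size.
#' @param threshold Decision threshold on the pre-ictal probability.
#' @return A tibble with `prob_preictal`, `pred`, and, when `ws` carries
#'   labels, `y`.
#' @export
predict_windows <- function(model, ws, batch_size = 256L, threshold = 0.5) {
  x <- if (inherits(ws, "window_set")) ws$x else ws
  n <- dim(x)[3]
  prob <- numeric(n)
  at <- 1L
  while (at <= n) {
    idx <- at:min(n, at + batch_size - 1L)
    out <- model_forward(model, x[, , idx, drop = FALSE], train = FALSE)
    prob[idx] <- out$probs[2, ]
    at <- at + batch_size
  }
  res <- tibble::tibble(prob_preictal = prob,
                        pred = as.integer(prob >= threshold))
  if (inherits(ws, "window_set")) res$y <- ws$meta$y
  res
}
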