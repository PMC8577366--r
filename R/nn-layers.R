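## Minimal neural-network layer primitives (forward + backward) used by the
## style-transfer networks. Activations are dense arrays dim (H, W, C, N);
## convolution kernels run in C++ (src/nn_ops.cpp). Parameter blocks are
## environments so running statistics and optimiser updates mutate in place.

as4d <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected an array")
  if (length(d) == 2) dim(x) <- c(d, 1L, 1L)
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  x
}

convLayerInit <- function(kh, kw, cin, cout, sd = 0.02) {
  e <- new.env(parent = emptyenv())
  e$W <- array(stats::rnorm(kh * kw * cin * cout, 0, sd), c(kh, kw, cin, cout))
  e$b <- numeric(cout)
  e
}

bnInit <- function(cout) {
  e <- new.env(parent = emptyenv())
  e$gamma <- rep(1, cout)
  e$beta <- numeric(cout)
  e$rm <- numeric(cout)
  e$rv <- rep(1, cout)
  e
}

convFw <- function(p, x, stride, pad) .conv_fw_cpp(x, p$W, p$b, stride, pad)
convBw <- function(p, x, gy, stride, pad) .conv_bw_cpp(x, p$W, gy, stride, pad)
convtFw <- function(p, x, stride, pad) .convt_fw_cpp(x, p$W, p$b, stride, pad)
convtBw <- function(p, x, gy, stride, pad) .convt_bw_cpp(x, p$W, gy, stride, pad)

leakyReluFw <- function(x, alpha) {
  y <- x
  neg <- x < 0
  y[neg] <- alpha * x[neg]
  list(y = y, neg = neg)
}
leakyReluBw <- function(cache, gy, alpha) {
  gx <- gy
  gx[cache$neg] <- alpha * gy[cache$neg]
  gx
}

reluFw <- function(x) {
  neg <- x < 0
  y <- x
  y[neg] <- 0
  list(y = y, neg = neg)
}
reluBw <- function(cache, gy) {
  gy[cache$neg] <- 0
  gy
}

# batch normalisation over (H, W, N) per channel
bnFw <- function(p, x, train, momentum, eps = 1e-5) {
  d <- dim(x)
  C <- d[3]
  xp <- aperm(x, c(1, 2, 4, 3))
  dim(xp) <- c(d[1] * d[2] * d[4], C)
  if (train) {
    mu <- colMeans(xp)
    xc <- sweep(xp, 2, mu)
    va <- colMeans(xc^2)
    p$rm <- momentum * p$rm + (1 - momentum) * mu
    p$rv <- momentum * p$rv + (1 - momentum) * va
  } else {
    mu <- p$rm
    va <- p$rv
    xc <- sweep(xp, 2, mu)
  }
  sdv <- sqrt(va + eps)
  xhat <- sweep(xc, 2, sdv, "/")
  y <- sweep(sweep(xhat, 2, p$gamma, "*"), 2, p$beta, "+")
  dim(y) <- c(d[1], d[2], d[4], C)
  y <- aperm(y, c(1, 2, 4, 3))
  list(y = y, cache = list(xhat = xhat, sdv = sdv, d = d, train = train))
}

bnBw <- function(p, cache, gy) {
  d <- cache$d
  C <- d[3]
  g <- aperm(gy, c(1, 2, 4, 3))
  dim(g) <- c(d[1] * d[2] * d[4], C)
  xhat <- cache$xhat
  ggamma <- colSums(g * xhat)
  gbeta <- colSums(g)
  m <- nrow(g)
  gxhat <- sweep(g, 2, p$gamma, "*")
  if (cache$train) {
    gx <- sweep(gxhat -
                  sweep(xhat, 2, colMeans(gxhat * xhat), "*") -
                  matrix(colMeans(gxhat), m, C, byrow = TRUE),
                2, cache$sdv, "/")
  } else {
    gx <- sweep(gxhat, 2, cache$sdv, "/")
  }
  dim(gx) <- c(d[1], d[2], d[4], C)
  gx <- aperm(gx, c(1, 2, 4, 3))
  list(gx = gx, ggamma = ggamma, gbeta = gbeta)
}

dropoutFw <- function(x, rate, train) {
  if (!train || rate <= 0) return(list(y = x, mask = NULL))
  keep <- 1 - rate
  mask <- array(stats::runif(length(x)) < keep, dim(x)) / keep
  list(y = x * mask, mask = mask)
}
dropoutBw <- function(cache, gy) {
  if (is.null(cache$mask)) gy else gy * cache$mask
}

tanhFw <- function(x) tanh(x)
tanhBw <- function(y, gy) gy * (1 - y^2)

# 2x2 average pooling
avgPoolFw <- function(x) {
  d <- dim(x)
  a <- array(x, c(2, d[1] / 2, 2, d[2] / 2, d[3], d[4]))
  y <- (a[1, , 1, , , , drop = FALSE] + a[2, , 1, , , , drop = FALSE] +
        a[1, , 2, , , , drop = FALSE] + a[2, , 2, , , , drop = FALSE]) / 4
  dim(y) <- c(d[1] / 2, d[2] / 2, d[3], d[4])
  y
}

concatCh <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(all(da[c(1, 2, 4)] == db[c(1, 2, 4)]))
  y <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  y[, , seq_len(da[3]), ] <- a
  y[, , da[3] + seq_len(db[3]), ] <- b
  y
}

splitCh <- function(g, c1) {
  list(a = g[, , seq_len(c1), , drop = FALSE],
       b = g[, , -seq_len(c1), , drop = FALSE])
}

## ---- Adam -------------------------------------------------------------

# collect (env, field) parameter references of a network in canonical order
paramRefs <- function(net) {
  refs <- list()
  addEnv <- function(e) {
    for (nm in intersect(c("W", "b", "gamma", "beta"), ls(e)))
      refs[[length(refs) + 1L]] <<- list(env = e, name = nm)
  }
  walk <- function(x) {
    if (is.environment(x)) addEnv(x)
    else if (is.list(x)) for (el in x) walk(el)
  }
  walk(net$blocks)
  refs
}

adamInit <- function(net) {
  refs <- paramRefs(net)
  list(t = 0L,
       m = lapply(refs, function(r) array(0, dim = dim(r$env[[r$name]]) %||%
                                            length(r$env[[r$name]]))),
       v = lapply(refs, function(r) array(0, dim = dim(r$env[[r$name]]) %||%
                                            length(r$env[[r$name]]))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# grads: flat list aligned with paramRefs(net)
adamStep <- function(net, grads, state, lr, beta1, beta2 = 0.999, eps = 1e-8) {
  refs <- paramRefs(net)
  stopifnot(length(refs) == length(grads))
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(refs)) {
    g <- grads[[i]]
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g^2
    r <- refs[[i]]
    upd <- lr * (state$m[[i]] / bc1) / (sqrt(state$v[[i]] / bc2) + eps)
    r$env[[r$name]] <- r$env[[r$name]] - upd
  }
  state
}
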