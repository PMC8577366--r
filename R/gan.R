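#' Style-transfer network configurations
#'
#' \code{ganGeneratorConfig} describes the U-Net generator that translates
#' 64 x 64 unstained-intensity patches into 32 x 32 EM maps: 5 downsampling
#' blocks (4 x 4 conv, stride 2, leaky ReLU alpha 0.2, batch normalisation
#' momentum 0.8 except in the first block) against 4 upsampling blocks
#' (transposed conv, ReLU, dropout, batch norm, skip concatenation) -- one
#' more down than up block because the input patch covers 400 um^2 while the
#' output map covers 100 um^2 -- and a final tanh convolution.
#' \code{ganTrainConfig} carries the adversarial training hyperparameters:
#' combined generator loss = 1 x adversarial MSE + 100 x reconstruction MAE,
#' Adam(lr 0.0002, beta1 0.5), batch size 16. The default epoch count
#' (10000) is the full-scale setting; pass a smaller value for desk-scale
#' runs.
#'
#' @param nDown,nUp down/upsampling block counts (nDown = nUp + 1).
#' @param baseFilters filters in the first block (doubling per depth, capped
#'   at 8x).
#' @param kernel sampling-layer kernel size.
#' @param leakyAlpha leaky-ReLU negative slope, in (0, 1).
#' @param bnMomentum batch-normalisation momentum.
#' @param dropoutRate generator up-block dropout rate.
#' @param inputSide,outputSide patch sides (powers of two, input = 2 x
#'   output).
#' @return a validated config list.
#' @export
ganGeneratorConfig <- function(nDown = 5L, nUp = 4L, baseFilters = 64L,
                               kernel = 4L, leakyAlpha = 0.2,
                               bnMomentum = 0.8, dropoutRate = 0.5,
                               inputSide = 64L, outputSide = 32L) {
  cfg <- list(nDown = as.integer(nDown), nUp = as.integer(nUp),
              baseFilters = as.integer(baseFilters), kernel = as.integer(kernel),
              leakyAlpha = leakyAlpha, bnMomentum = bnMomentum,
              dropoutRate = dropoutRate, inputSide = as.integer(inputSide),
              outputSide = as.integer(outputSide))
  if (cfg$inputSide != 2L * cfg$outputSide)
    stop("invalid config: inputSide must equal 2 * outputSide")
  if (cfg$nDown != cfg$nUp + 1L)
    stop("invalid config: nDown must equal nUp + 1")
  if (leakyAlpha <= 0 || leakyAlpha >= 1)
    stop("invalid config: leakyAlpha must be in (0, 1)")
  if (bitwAnd(cfg$inputSide, cfg$inputSide - 1L) != 0L)
    stop("invalid config: sides must be powers of two")
  if (cfg$inputSide / 2^cfg$nDown < 1)
    stop("invalid config: too many downsampling blocks for the input side")
  cfg
}

#' @rdname ganGeneratorConfig
#' @param batchSize minibatch size.
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param beta1 Adam first-moment decay.
#' @param lossWeights named numeric c(adversarial, reconstruction).
#' @param seed integer training seed.
#' @export
ganTrainConfig <- function(batchSize = 16L, epochs = 10000L, lr = 2e-4,
                           beta1 = 0.5,
                           lossWeights = c(adversarial = 1,
                                           reconstruction = 100),
                           seed = 1L) {
  if (batchSize < 1 || epochs < 1 || lr <= 0 || beta1 <= 0 || beta1 >= 1)
    stop("invalid training config")
  if (any(lossWeights < 0)) stop("loss weights must be >= 0")
  list(batchSize = as.integer(batchSize), epochs = as.integer(epochs),
       lr = lr, beta1 = beta1, lossWeights = lossWeights,
       seed = as.integer(seed))
}

genFilters <- function(cfg) {
  as.integer(cfg$baseFilters * pmin(2^(seq_len(cfg$nDown) - 1), 8))
}

#' Build the generator / discriminator networks
#'
#' \code{buildGenerator} assembles the U-Net generator (weights initialised
#' N(0, 0.02)); \code{buildDiscriminator} the PatchGAN discriminator, which
#' average-pools the 64 x 64 input patch to 32 x 32, concatenates the EM map
#' and applies four strided conv blocks (leaky ReLU 0.2, batch norm except
#' the first, dropout 0.25) before a final convolutional validity layer.
#'
#' @param cfg a \code{\link{ganGeneratorConfig}}.
#' @param seed integer seed for weight initialisation.
#' @return a network descriptor list (architecture config plus parameter
#'   blocks); consumed by \code{\link{trainGan}} and
#'   \code{\link{predictWholeSample}}.
#' @export
buildGenerator <- function(cfg = ganGeneratorConfig(), seed = 1L) {
  f <- genFilters(cfg)
  k <- cfg$kernel
  withSeed(seed, {
    down <- vector("list", cfg$nDown)
    cin <- 1L
    for (i in seq_len(cfg$nDown)) {
      down[[i]] <- list(conv = convLayerInit(k, k, cin, f[i]),
                        bn = if (i > 1) bnInit(f[i]))
      cin <- f[i]
    }
    up <- vector("list", cfg$nUp)
    hch <- f[cfg$nDown]                      # bottleneck channels
    for (i in seq_len(cfg$nUp)) {
      fout <- f[cfg$nDown - i]
      up[[i]] <- list(conv = convLayerInit(k, k, hch, fout),
                      bn = bnInit(fout))
      hch <- fout + f[cfg$nDown - i]         # after skip concatenation
    }
    final <- convLayerInit(3L, 3L, hch, 1L)
    blocks <- list()
    for (b in down) blocks <- c(blocks, list(b$conv), if (!is.null(b$bn)) list(b$bn))
    for (b in up) blocks <- c(blocks, list(b$conv), list(b$bn))
    blocks <- c(blocks, list(final))
    list(cfg = cfg, down = down, up = up, final = final, blocks = blocks)
  })
}

#' @rdname buildGenerator
#' @param nBlocks discriminator conv blocks.
#' @param dropoutRate discriminator dropout rate.
#' @export
buildDiscriminator <- function(cfg = ganGeneratorConfig(), nBlocks = 4L,
                               dropoutRate = 0.25, seed = 2L) {
  f <- as.integer(cfg$baseFilters * pmin(2^(seq_len(nBlocks) - 1), 8))
  k <- cfg$kernel
  withSeed(seed, {
    blocksL <- vector("list", nBlocks)
    cin <- 2L                                # pooled image + EM map
    for (i in seq_len(nBlocks)) {
      blocksL[[i]] <- list(conv = convLayerInit(k, k, cin, f[i]),
                           bn = if (i > 1) bnInit(f[i]))
      cin <- f[i]
    }
    final <- convLayerInit(3L, 3L, cin, 1L)
    blocks <- list()
    for (b in blocksL) blocks <- c(blocks, list(b$conv), if (!is.null(b$bn)) list(b$bn))
    blocks <- c(blocks, list(final))
    list(cfg = cfg, nBlocks = nBlocks, dropoutRate = dropoutRate,
         body = blocksL, final = final, blocks = blocks)
  })
}

## ---- generator forward / backward ------------------------------------

genForward <- function(gen, x, train = TRUE) {
  cfg <- gen$cfg
  caches <- list(down = vector("list", cfg$nDown),
                 up = vector("list", cfg$nUp))
  skips <- vector("list", cfg$nDown)
  h <- x
  for (i in seq_len(cfg$nDown)) {
    p <- gen$down[[i]]
    cv <- convFw(p$conv, h, 2L, 1L)
    lr <- leakyReluFw(cv, cfg$leakyAlpha)
    if (!is.null(p$bn)) {
      bn <- bnFw(p$bn, lr$y, train, cfg$bnMomentum)
      out <- bn$y
    } else bn <- NULL
    if (is.null(bn)) out <- lr$y
    caches$down[[i]] <- list(xin = h, lr = lr, bn = bn)
    skips[[i]] <- out
    h <- out
  }
  for (i in seq_len(cfg$nUp)) {
    p <- gen$up[[i]]
    tv <- convtFw(p$conv, h, 2L, 1L)
    rl <- reluFw(tv)
    dr <- dropoutFw(rl$y, cfg$dropoutRate, train)
    bn <- bnFw(p$bn, dr$y, train, cfg$bnMomentum)
    skip <- skips[[cfg$nDown - i]]
    caches$up[[i]] <- list(xin = h, rl = rl, dr = dr, bn = bn,
                           nOwn = dim(bn$y)[3])
    h <- concatCh(bn$y, skip)
  }
  fv <- convFw(gen$final, h, 1L, 1L)
  y <- tanhFw(fv)
  caches$final <- list(xin = h, y = y)
  list(y = y, caches = caches)
}

genBackward <- function(gen, caches, gy) {
  cfg <- gen$cfg
  gradsDown <- vector("list", cfg$nDown)   # each: list(conv = list(gW, gb), bn = ...)
  gradsUp <- vector("list", cfg$nUp)
  g <- tanhBw(caches$final$y, gy)
  fb <- convBw(gen$final, caches$final$xin, g, 1L, 1L)
  gradsFinal <- list(gW = fb$gw, gb = fb$gb)
  g <- fb$gx
  gSkip <- vector("list", cfg$nDown)       # gradients flowing into skip outputs
  for (i in rev(seq_len(cfg$nUp))) {
    cc <- caches$up[[i]]
    sp <- splitCh(g, cc$nOwn)
    si <- cfg$nDown - i
    gSkip[[si]] <- if (is.null(gSkip[[si]])) sp$b else gSkip[[si]] + sp$b
    p <- gen$up[[i]]
    bb <- bnBw(p$bn, cc$bn$cache, sp$a)
    gd <- dropoutBw(cc$dr, bb$gx)
    gr <- reluBw(cc$rl, gd)
    tb <- convtBw(p$conv, cc$xin, gr, 2L, 1L)
    gradsUp[[i]] <- list(conv = list(gW = tb$gw, gb = tb$gb),
                         bn = list(ggamma = bb$ggamma, gbeta = bb$gbeta))
    g <- tb$gx
  }
  for (i in rev(seq_len(cfg$nDown))) {
    cc <- caches$down[[i]]
    gout <- g
    if (!is.null(gSkip[[i]])) gout <- gout + gSkip[[i]]
    p <- gen$down[[i]]
    if (!is.null(p$bn)) {
      bb <- bnBw(p$bn, cc$bn$cache, gout)
      gbn <- list(ggamma = bb$ggamma, gbeta = bb$gbeta)
      gout <- bb$gx
    } else gbn <- NULL
    gl <- leakyReluBw(cc$lr, gout, cfg$leakyAlpha)
    cb <- convBw(p$conv, cc$xin, gl, 2L, 1L)
    gradsDown[[i]] <- list(conv = list(gW = cb$gw, gb = cb$gb), bn = gbn)
    g <- cb$gx
  }
  flat <- list()
  for (b in gradsDown) {
    flat <- c(flat, list(b$conv$gW, b$conv$gb))
    if (!is.null(b$bn)) flat <- c(flat, list(b$bn$ggamma, b$bn$gbeta))
  }
  for (b in gradsUp) {
    flat <- c(flat, list(b$conv$gW, b$conv$gb, b$bn$ggamma, b$bn$gbeta))
  }
  flat <- c(flat, list(gradsFinal$gW, gradsFinal$gb))
  list(flat = flat, gx = g)
}

## ---- discriminator forward / backward --------------------------------

discForward <- function(disc, ximg, em, train = TRUE) {
  cfg <- disc$cfg
  pooled <- avgPoolFw(ximg)
  h <- concatCh(pooled, em)
  caches <- vector("list", disc$nBlocks)
  for (i in seq_len(disc$nBlocks)) {
    p <- disc$body[[i]]
    cv <- convFw(p$conv, h, 2L, 1L)
    lr <- leakyReluFw(cv, cfg$leakyAlpha)
    if (!is.null(p$bn)) {
      bn <- bnFw(p$bn, lr$y, train, cfg$bnMomentum)
      out <- bn$y
    } else { bn <- NULL; out <- lr$y }
    dr <- dropoutFw(out, disc$dropoutRate, train)
    caches[[i]] <- list(xin = h, lr = lr, bn = bn, dr = dr)
    h <- dr$y
  }
  v <- convFw(disc$final, h, 1L, 1L)
  list(v = v, caches = caches, finalIn = h)
}

discBackward <- function(disc, fw, gv) {
  fb <- convBw(disc$final, fw$finalIn, gv, 1L, 1L)
  g <- fb$gx
  grads <- vector("list", disc$nBlocks)
  for (i in rev(seq_len(disc$nBlocks))) {
    cc <- fw$caches[[i]]
    p <- disc$body[[i]]
    gd <- dropoutBw(cc$dr, g)
    if (!is.null(p$bn)) {
      bb <- bnBw(p$bn, cc$bn$cache, gd)
      gbn <- list(ggamma = bb$ggamma, gbeta = bb$gbeta)
      gd <- bb$gx
    } else gbn <- NULL
    gl <- leakyReluBw(cc$lr, gd, disc$cfg$leakyAlpha)
    cb <- convBw(p$conv, cc$xin, gl, 2L, 1L)
    grads[[i]] <- list(conv = list(gW = cb$gw, gb = cb$gb), bn = gbn)
    g <- cb$gx
  }
  gEm <- g[, , 2L, , drop = FALSE]          # gradient wrt the EM input channel
  flat <- list()
  for (b in grads) {
    flat <- c(flat, list(b$conv$gW, b$conv$gb))
    if (!is.null(b$bn)) flat <- c(flat, list(b$bn$ggamma, b$bn$gbeta))
  }
  flat <- c(flat, list(fb$gw, fb$gb))
  list(flat = flat, gEm = gEm)
}

sumFlat <- function(a, b) mapply(function(x, y) x + y, a, b, SIMPLIFY = FALSE)
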