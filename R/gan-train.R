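#' Stack training pairs into network arrays
#'
#' @param pairs list of \linkS4class{TrainingPair}.
#' @return list of arrays \code{x} (64, 64, 1, N) and \code{y} (32, 32, 1, N)
#'   on the [-1, 1] scale.
#' @export
pairsToArrays <- function(pairs) {
  n <- length(pairs)
  x <- array(0, c(64, 64, 1, n))
  y <- array(0, c(32, 32, 1, n))
  for (i in seq_len(n)) {
    x[, , 1, i] <- pairs[[i]]@imagePatch
    y[, , 1, i] <- pairs[[i]]@emMap
  }
  list(x = x, y = y)
}

#' Train the conditional style-transfer GAN
#'
#' Alternating adversarial training of the generator and discriminator on
#' registered image/EM-map pairs. Per batch the discriminator is updated to
#' separate measured from generated EM maps (least-squares adversarial loss),
#' then the generator is updated on the combined objective
#' \code{wAdv * MSE(D(x, G(x)), 1) + wRec * MAE(G(x), y)} with weights 1 and
#' 100. Both networks use Adam (lr 0.0002, beta1 0.5). The loss trajectory is
#' reproducible given the training seed. A non-finite loss aborts with the
#' epoch index.
#'
#' @param pairs training pairs (list of \linkS4class{TrainingPair}), at least
#'   one batch.
#' @param genConfig a \code{\link{ganGeneratorConfig}}.
#' @param trainConfig a \code{\link{ganTrainConfig}}.
#' @param valPairs optional validation pairs; when given, the per-epoch
#'   masked validation MAE (kPa) is recorded and the best-epoch weights are
#'   kept.
#' @param checkpointDir optional directory; the (best) generator is saved
#'   there as \code{generator.rds} with a JSON architecture manifest.
#' @param verbose print per-epoch losses.
#' @return a list: \code{generator} (trained network; best-epoch weights if
#'   validation pairs were given), \code{discriminator}, \code{history}
#'   data.frame (epoch, dLoss, gAdv, gRec, valMae).
#' @export
trainGan <- function(pairs, genConfig = ganGeneratorConfig(),
                     trainConfig = ganTrainConfig(), valPairs = NULL,
                     checkpointDir = NULL, verbose = FALSE) {
  if (length(pairs) < 1) stop("empty pair set")
  tc <- trainConfig
  arr <- pairsToArrays(pairs)
  val <- if (!is.null(valPairs)) pairsToArrays(valPairs)
  n <- dim(arr$x)[4]
  wAdv <- tc$lossWeights[["adversarial"]]
  wRec <- tc$lossWeights[["reconstruction"]]
  gen <- buildGenerator(genConfig, seed = childSeed(tc$seed, 1))
  disc <- buildDiscriminator(genConfig, seed = childSeed(tc$seed, 2))
  stG <- adamInit(gen)
  stD <- adamInit(disc)
  hist <- data.frame(epoch = integer(), dLoss = numeric(), gAdv = numeric(),
                     gRec = numeric(), valMae = numeric())
  best <- list(mae = Inf, params = NULL)
  withSeed(childSeed(tc$seed, 3), {
    for (ep in seq_len(tc$epochs)) {
      ord <- sample.int(n)
      eD <- eA <- eR <- 0; nb <- 0L
      for (b0 in seq(1, n, by = tc$batchSize)) {
        idx <- ord[b0:min(b0 + tc$batchSize - 1, n)]
        xb <- arr$x[, , , idx, drop = FALSE]
        yb <- arr$y[, , , idx, drop = FALSE]
        # --- discriminator update
        fake <- genForward(gen, xb, train = TRUE)$y
        fwR <- discForward(disc, xb, yb, train = TRUE)
        fwF <- discForward(disc, xb, fake, train = TRUE)
        m <- length(fwR$v)
        lossD <- 0.5 * (mean((fwR$v - 1)^2) + mean(fwF$v^2))
        gR <- discBackward(disc, fwR, (fwR$v - 1) / m)
        gF <- discBackward(disc, fwF, fwF$v / m)
        stD <- adamStep(disc, sumFlat(gR$flat, gF$flat), stD, tc$lr, tc$beta1)
        # --- generator update (discriminator frozen)
        gfw <- genForward(gen, xb, train = TRUE)
        fwG <- discForward(disc, xb, gfw$y, train = TRUE)
        mg <- length(fwG$v)
        lossAdv <- mean((fwG$v - 1)^2)
        diff <- gfw$y - yb
        lossRec <- mean(abs(diff))
        gAdvEm <- discBackward(disc, fwG, 2 * (fwG$v - 1) / mg)$gEm
        gOut <- wAdv * gAdvEm + wRec * sign(diff) / length(diff)
        gb <- genBackward(gen, gfw$caches, gOut)
        stG <- adamStep(gen, gb$flat, stG, tc$lr, tc$beta1)
        if (!is.finite(lossD) || !is.finite(lossAdv) || !is.finite(lossRec))
          stop(sprintf("non-finite loss at epoch %d", ep))
        eD <- eD + lossD; eA <- eA + lossAdv; eR <- eR + lossRec
        nb <- nb + 1L
      }
      vm <- NA_real_
      if (!is.null(val)) {
        pred <- genForward(gen, val$x, train = FALSE)$y
        vm <- mean(abs(unscaleEM(pred) - unscaleEM(val$y)))
        if (vm < best$mae)
          best <- list(mae = vm, params = snapshotParams(gen))
      }
      hist <- rbind(hist, data.frame(epoch = ep, dLoss = eD / nb,
                                     gAdv = eA / nb, gRec = eR / nb,
                                     valMae = vm))
      if (verbose)
        message(sprintf("epoch %d: D %.4f, adv %.4f, rec %.4f, val MAE %.4f",
                        ep, eD / nb, eA / nb, eR / nb, vm))
    }
  })
  if (!is.null(best$params)) restoreParams(gen, best$params)
  if (!is.null(checkpointDir)) saveGenerator(gen, checkpointDir)
  list(generator = gen, discriminator = disc, history = hist)
}

# deep-copy / restore parameter environments (for best-epoch checkpointing)
snapshotParams <- function(net) {
  lapply(net$blocks, function(e) as.list(e))
}
restoreParams <- function(net, snap) {
  for (i in seq_along(net$blocks)) {
    e <- net$blocks[[i]]
    for (nm in names(snap[[i]])) e[[nm]] <- snap[[i]][[nm]]
  }
  invisible(net)
}

#' Save / load a trained generator
#'
#' The generator is serialised as an RDS checkpoint plus a JSON architecture
#' manifest describing the configuration.
#'
#' @param gen a generator from \code{\link{trainGan}} /
#'   \code{\link{buildGenerator}}.
#' @param dir checkpoint directory.
#' @return \code{saveGenerator} returns \code{dir} invisibly;
#'   \code{loadGenerator} the generator.
#' @export
saveGenerator <- function(gen, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(list(cfg = gen$cfg, params = snapshotParams(gen)),
          file.path(dir, "generator.rds"))
  jsonlite::write_json(gen$cfg, file.path(dir, "architecture.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname saveGenerator
#' @export
loadGenerator <- function(dir) {
  obj <- readRDS(file.path(dir, "generator.rds"))
  gen <- buildGenerator(do.call(ganGeneratorConfig, obj$cfg), seed = 1L)
  restoreParams(gen, obj$params)
  gen
}

#' Run the generator on a batch of input patches
#'
#' Inference-mode forward pass (running batch-norm statistics, no dropout).
#'
#' @param gen generator network.
#' @param x array (64, 64, 1, N) of scaled input patches, or a single 64 x 64
#'   matrix.
#' @return array (32, 32, 1, N) of EM maps on the [-1, 1] scale.
#' @export
predictPatches <- function(gen, x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L, 1L)
  genForward(gen, x, train = FALSE)$y
}
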