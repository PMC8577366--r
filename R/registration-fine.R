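#' Resample to the common fine registration grid
#'
#' The AFM grid pitch (1.25 um) and camera pixel (1.625 um) differ by the
#' rational ratio 13/10, so both are upscaled by bilinear interpolation to a
#' matched pixel size of 0.125 um: image patches by 13x, EM/topology maps by
#' 10x (an 8 x 8 map becomes the 80 x 80 pixel measurement area). Pixel sizes
#' must be exact integer multiples of the target; otherwise the call is
#' rejected with the computed ratio.
#'
#' @param x numeric matrix (NaN allowed; NaN cells stay NaN where the nearest
#'   source pixel is NaN).
#' @param pixelSize input pixel size, um.
#' @param targetPixelSize output pixel size, um (default 0.125).
#' @return matrix upscaled by the integer ratio.
#' @export
resampleToCommonGrid <- function(x, pixelSize, targetPixelSize = 0.125) {
  ratio <- pixelSize / targetPixelSize
  if (abs(ratio - round(ratio)) > 1e-9)
    stop(sprintf("pixel sizes not commensurate: ratio %.6f is not an integer",
                 ratio))
  ratio <- as.integer(round(ratio))
  if (ratio == 1L) return(x)
  resampleBilinear(x, pixelSize, targetPixelSize,
                   outDim = dim(x) * ratio)
}

#' Sliding-window mutual information map
#'
#' Computes the mutual information (bits) between the upscaled topology map
#' and the image patch as a function of the displacement of the topology map
#' relative to the patch, in the manner of 2-D cross-correlation. At each
#' displacement the joint histogram of (intensity, height) over the overlap
#' window uses 32 equal-width bins per variable spanning that window's
#' min-max range; NaN topology cells are excluded pairwise, and displacements
#' with fewer than \code{minPairs} valid pairs are marked invalid (NA).
#'
#' @param topologyUp upscaled topology map (e.g. 80 x 80 at 0.125 um), NaN
#'   allowed.
#' @param patchUp upscaled (contrast-enhanced) image patch; must contain the
#'   topology map.
#' @param nBins histogram bins per variable.
#' @param minPairs minimum valid pixel pairs per displacement.
#' @return a list: \code{mi} matrix over displacements (row/col 1 = topology
#'   aligned with the patch top-left), \code{argmax} c(row, col) or NULL if
#'   all displacements are invalid, \code{value} the maximum MI.
#' @export
mutualInformationMap <- function(topologyUp, patchUp, nBins = 32,
                                 minPairs = 100) {
  if (any(dim(topologyUp) > dim(patchUp)))
    stop("topology map must fit inside the patch")
  mi <- .mi_map_cpp(patchUp, topologyUp, as.integer(nBins),
                    as.integer(minPairs))
  pk <- argmaxRC(mi, tol = 1e-12)
  list(mi = mi, argmax = pk,
       value = if (is.null(pk)) NA_real_ else mi[pk[1], pk[2]])
}

#' Fine localisation of the measurement area within a coarse patch
#'
#' Refines a coarsely localised site: a ~30 um patch around the coarse
#' estimate is contrast enhanced (CLAHE) and upscaled to 0.125 um, the site's
#' 8 x 8 topology map is upscaled to 80 x 80, and the 80 x 80 region of the
#' patch with maximum mutual information is taken as the finely localised
#' measurement area. If every displacement is invalid the coarse centre is
#' returned with a warning (fallback).
#'
#' @param patch image patch at the camera pixel size (matrix), extracted
#'   around the coarse estimate.
#' @param topology the site's topology grid (e.g. the \code{topology} slot of
#'   a \linkS4class{ForceMap}), at the AFM grid pitch.
#' @param cameraPixel patch pixel size, um.
#' @param pitch topology pixel size, um.
#' @param claheWindow CLAHE window in (upscaled) pixels.
#' @param nBins,minPairs forwarded to \code{\link{mutualInformationMap}}.
#' @return a list: \code{offset} c(row, col) 1-based top-left of the 80 x 80
#'   area within the upscaled patch, \code{region} the localised 80 x 80
#'   intensity area, \code{patchUp} the upscaled (non-equalised) patch --
#'   contrast enhancement is applied only inside the MI similarity
#'   computation, where only structural alignment matters -- \code{mi} the MI
#'   map, \code{fallback} logical.
#' @export
fineLocalizeArea <- function(patch, topology, cameraPixel = 1.625,
                             pitch = 1.25, claheWindow = 32, nBins = 32,
                             minPairs = 100) {
  patchEq <- applyClahe(patch, min(claheWindow, min(dim(patch))))
  patchUp <- resampleToCommonGrid(patch, cameraPixel)
  patchUpEq <- resampleToCommonGrid(patchEq, cameraPixel)
  topoUp <- resampleToCommonGrid(topology, pitch)
  res <- mutualInformationMap(topoUp, patchUpEq, nBins, minPairs)
  if (is.null(res$argmax)) {
    warning("all displacements invalid; falling back to the coarse centre")
    off <- floor((dim(patchUp) - dim(topoUp)) / 2) + 1L
    fb <- TRUE
  } else {
    off <- res$argmax
    fb <- FALSE
  }
  region <- patchUp[off[1]:(off[1] + nrow(topoUp) - 1L),
                    off[2]:(off[2] + ncol(topoUp) - 1L)]
  list(offset = off, region = region, patchUp = patchUp, mi = res$mi,
       fallback = fb)
}

#' Extract a training pair from a finely localised site
#'
#' Builds the network training pair for one measurement site: the 20 um x
#' 20 um image context centred on the 80 x 80 localised area (160 x 160 at
#' 0.125 um) is downsampled to 64 x 64 (2x bilinear interpolation to a common
#' multiple, then 5 x 5 local-mean block averaging), and the site's 8 x 8 EM
#' map is rendered at 32 x 32 (0.3125 um output pixels). Both are scaled to
#' [-1, 1], EM clamped to [0, 2] kPa first. EM maps with NaN cells are
#' imputed by the nearest valid neighbour when at most \code{maxNaNFrac} of
#' cells are NaN; otherwise the site is discarded (returns NULL with a
#' message).
#'
#' @param fine result of \code{\link{fineLocalizeArea}}.
#' @param emMap the site's 8 x 8 EM grid in kPa (NaN allowed).
#' @param sampleId,siteId provenance strings.
#' @param maxNaNFrac maximum tolerated NaN fraction in \code{emMap}.
#' @return a \linkS4class{TrainingPair}, or NULL if the site is discarded
#'   (context out of bounds or too many NaNs).
#' @export
extractTrainingPair <- function(fine, emMap, sampleId = "S000",
                                siteId = "site", maxNaNFrac = 0.2) {
  off <- fine$offset
  pu <- fine$patchUp
  areaSide <- 80L
  ctxMargin <- 40L               # (160 - 80) / 2 at 0.125 um
  r0 <- off[1] - ctxMargin
  c0 <- off[2] - ctxMargin
  if (r0 < 1 || c0 < 1 || r0 + 159L > nrow(pu) || c0 + 159L > ncol(pu)) {
    message(sprintf("site %s/%s: 20 um context exceeds patch bounds; skipped",
                    sampleId, siteId))
    return(NULL)
  }
  ctx <- pu[r0:(r0 + 159L), c0:(c0 + 159L)]
  img64 <- blockMean(resampleBilinear(ctx, 1, 0.5, outDim = c(320L, 320L)), 5L)
  nanFrac <- mean(is.na(emMap))
  if (nanFrac > maxNaNFrac) {
    message(sprintf("site %s/%s: %.0f%% NaN EM cells; site discarded",
                    sampleId, siteId, 100 * nanFrac))
    return(NULL)
  }
  if (nanFrac > 0) emMap <- imputeNearest(emMap)
  em32 <- resampleBilinear(emMap, 10 / nrow(emMap), 10 / 32,
                           outDim = c(32L, 32L))
  new("TrainingPair",
      imagePatch = scaleIntensity(img64),
      emMap = scaleEM(em32),
      sampleId = sampleId, siteId = siteId,
      fineOffset = as.numeric(off))
}

# nearest-valid-neighbour imputation on a small grid
imputeNearest <- function(m) {
  bad <- which(is.na(m), arr.ind = TRUE)
  if (!nrow(bad)) return(m)
  good <- which(!is.na(m), arr.ind = TRUE)
  if (!nrow(good)) stop("no valid cells to impute from")
  out <- m
  for (k in seq_len(nrow(bad))) {
    d2 <- (good[, 1] - bad[k, 1])^2 + (good[, 2] - bad[k, 2])^2
    g <- good[which.min(d2), , drop = FALSE]
    out[bad[k, 1], bad[k, 2]] <- m[g[1, 1], g[1, 2]]
  }
  out
}

#' Train/validation split of training pairs
#'
#' Partitions pairs into training and validation sets, reproducibly given the
#' seed. The default splits by sample id -- all sites of a held-out sample
#' stay together, preventing leakage between sites of the same section --
#' targeting the requested fraction of *pairs* greedily over shuffled
#' samples. \code{by = "pair"} splits at the pair level exactly
#' (\code{round(fraction * n)} training pairs).
#'
#' @param pairs list of \linkS4class{TrainingPair}.
#' @param fraction training fraction in (0, 1).
#' @param seed integer seed.
#' @param by \code{"sample"} (default) or \code{"pair"}.
#' @return a list with \code{train} and \code{validation} pair lists.
#' @export
splitDataset <- function(pairs, fraction = 0.8, seed = 1L,
                         by = c("sample", "pair")) {
  by <- match.arg(by)
  if (length(pairs) < 2) stop("need at least 2 pairs")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  n <- length(pairs)
  if (by == "pair") {
    idx <- withSeed(seed, sample.int(n))
    nTr <- round(fraction * n)
    nTr <- min(max(nTr, 1L), n - 1L)
    return(list(train = pairs[sort(idx[seq_len(nTr)])],
                validation = pairs[sort(idx[-seq_len(nTr)])]))
  }
  sids <- vapply(pairs, function(p) p@sampleId, character(1))
  us <- unique(sids)
  ord <- withSeed(seed, sample(us))
  target <- fraction * n
  cum <- cumsum(table(sids)[ord])
  # add samples while it brings the train count closer to the target
  k <- which.min(abs(cum - target))
  k <- min(max(k, 1L), length(us) - 1L)
  trainSamples <- ord[seq_len(k)]
  list(train = pairs[sids %in% trainSamples],
       validation = pairs[!sids %in% trainSamples])
}
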