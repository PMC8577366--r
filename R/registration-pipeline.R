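#' Extract the coarse search patch around a site estimate
#'
#' Cuts the ~30 um x 30 um patch (19 x 19 camera pixels at 1.625 um) centred
#' on a coarse site estimate out of the whole-sample image; the extra margin
#' over the 10 um measurement area absorbs coarse-registration error.
#'
#' @param wholeImage whole-sample \linkS4class{MicroscopyImage}.
#' @param centerUm c(y, x) coarse site centre in um.
#' @param halfPx patch half-size in pixels (default 9, i.e. 19 x 19).
#' @return list with \code{patch} (matrix) and \code{topLeftUm}, the physical
#'   position of the patch's top-left corner.
#' @export
extractCoarsePatch <- function(wholeImage, centerUm, halfPx = 9L) {
  ps <- wholeImage@pixelSize
  pc <- round(centerUm / ps + 0.5)     # pixel index containing the centre
  d <- dim(wholeImage@pixels)
  if (any(pc - halfPx < 1) || any(pc + halfPx > d))
    stop("coarse patch exceeds the whole-sample image")
  rows <- (pc[1] - halfPx):(pc[1] + halfPx)
  cols <- (pc[2] - halfPx):(pc[2] + halfPx)
  list(patch = wholeImage@pixels[rows, cols],
       topLeftUm = c((pc[1] - halfPx - 1) * ps, (pc[2] - halfPx - 1) * ps))
}

#' Register one measurement site end to end
#'
#' Full localisation of a single site on a synthetic scene: render the
#' cantilever-occluded FOV, coarse NCC localisation, coarse patch extraction,
#' then fine mutual-information localisation against the site's measured
#' topology. Returns the fine site centre and everything needed to build the
#' training pair.
#'
#' @param wholeImage whole-sample \linkS4class{MicroscopyImage}.
#' @param siteCenter true site centre in um (used only to render the scene).
#' @param forceMap the site's processed \linkS4class{ForceMap}.
#' @param template4x \linkS4class{CantileverTemplate} at 4x.
#' @param fovUm FOV extent for the rendered scene, um.
#' @param seed integer seed for the scene noise.
#' @return a list: \code{coarse} (coarse localisation result), \code{fine}
#'   (fine localisation result), \code{fineCenterUm} the registered centre,
#'   \code{patchTopLeftUm}.
#' @export
registerSite <- function(wholeImage, siteCenter, forceMap, template4x,
                         fovUm = c(400, 400), seed = 1L) {
  scene <- renderAfmFov(wholeImage, siteCenter, template4x, fovUm,
                        seed = seed)
  coarse <- coarseLocalizeSite(scene$fov, template4x, wholeImage)
  cp <- extractCoarsePatch(wholeImage, coarse$centerUm)
  fine <- fineLocalizeArea(cp$patch, forceMap@topology,
                           cameraPixel = wholeImage@pixelSize,
                           pitch = forceMap@pitch)
  fineCenter <- cp$topLeftUm + (fine$offset - 1) * 0.125 + 5
  list(coarse = coarse, fine = fine, fineCenterUm = fineCenter,
       patchTopLeftUm = cp$topLeftUm)
}

#' Build training pairs from a synthetic cohort
#'
#' Converts every usable measurement site of a cohort into a
#' \linkS4class{TrainingPair}. With \code{register = TRUE} the full pipeline
#' runs per site (FOV rendering, coarse NCC, fine MI registration); with
#' \code{register = FALSE} the generator's planted site positions are used
#' directly (exact registration), which isolates the network-training stage
#' from registration error and is much faster.
#'
#' @param cohort a \linkS4class{TissueCohort} generated with images and force
#'   maps.
#' @param config an \linkS4class{AcquisitionConfig}.
#' @param register logical; run the registration stages per site.
#' @param template4x cantilever template (required when registering).
#' @param fovUm FOV extent for rendered scenes.
#' @return list of \linkS4class{TrainingPair} (discarded sites are dropped).
#' @export
cohortTrainingPairs <- function(cohort, config = acquisitionConfig(),
                                register = FALSE, template4x = NULL,
                                fovUm = c(400, 400)) {
  pairs <- list()
  for (smp in cohort@samples) {
    if (is.null(smp$image) || is.null(smp$sites))
      stop("cohort must be generated with images and force maps")
    img <- smp$image
    for (st in smp$sites) {
      fm <- processForceMap(st$curves, config, siteId = st$siteId,
                            siteCenter = st$siteCenter)
      if (register) {
        if (is.null(template4x)) stop("template4x required when register = TRUE")
        reg <- tryCatch(
          registerSite(img, st$siteCenter, fm, template4x, fovUm,
                       seed = childSeed(cohort@seed, length(pairs) + 1L)),
          error = function(e) NULL)
        if (is.null(reg)) next
        fine <- reg$fine
      } else {
        cp <- tryCatch(extractCoarsePatch(img, st$siteCenter),
                       error = function(e) NULL)
        if (is.null(cp)) next
        patchUp <- resampleToCommonGrid(cp$patch, img@pixelSize)
        r0 <- round((st$siteCenter - 5 - cp$topLeftUm) / 0.125) + 1
        fine <- list(offset = r0, patchUp = patchUp, fallback = FALSE)
      }
      tp <- extractTrainingPair(fine, fm@em, sampleId = smp$sampleId,
                                siteId = st$siteId)
      if (!is.null(tp)) pairs[[length(pairs) + 1L]] <- tp
    }
  }
  pairs
}
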