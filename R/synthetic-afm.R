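#' Hertz spherical-indenter force law
#'
#' Closed-form contact force for a rigid sphere of radius R indenting an
#' elastic half-space: \code{F = (4/3) * E / (1 - nu^2) * sqrt(R) * d^(3/2)}.
#' With E in kPa, R and d in um the force comes out directly in nN
#' (kPa * um^2 = nN).
#'
#' @param E elastic modulus, kPa.
#' @param delta indentation depth(s), um.
#' @param beadRadius indenter radius, um.
#' @param poissonRatio Poisson ratio.
#' @return force in nN, same length as \code{delta}.
#' @examples
#' hertzForce(1, 1)   # (4/3) * (1/0.75) * sqrt(5)
#' @export
hertzForce <- function(E, delta, beadRadius = 5, poissonRatio = 0.5) {
  (4 / 3) * (E / (1 - poissonRatio^2)) * sqrt(beadRadius) * delta^1.5
}

#' Simulate a single force-indentation curve
#'
#' Samples the Hertz spherical-indenter law on a uniform indentation grid,
#' stopping at whichever comes first of the maximum indentation depth or the
#' force setpoint, and adds Gaussian force noise. The first sample is at zero
#' indentation (zero ideal force).
#'
#' @param E true elastic modulus at the point, kPa (>= 0).
#' @param config an \linkS4class{AcquisitionConfig}.
#' @param noiseSd force noise SD in nN.
#' @param contactOffset axial contact-point offset in um recorded with the
#'   curve (used downstream as the topology estimate).
#' @param deltaStep indentation sampling step in um.
#' @param seed integer seed.
#' @return a \linkS4class{ForceCurve}.
#' @export
simulateForceCurve <- function(E, config = acquisitionConfig(),
                               noiseSd = 0.01, contactOffset = 0,
                               deltaStep = 0.02, seed = 1L) {
  if (!is.finite(E) || E < 0) stop("E must be >= 0")
  delta <- seq(0, config@maxIndentation, by = deltaStep)
  f <- hertzForce(E, delta, config@beadRadius, config@poissonRatio)
  keep <- f <= config@forceSetpoint
  if (!all(keep)) {             # truncate at the setpoint
    last <- which(!keep)[1] - 1L
    delta <- delta[seq_len(last)]
    f <- f[seq_len(last)]
  }
  if (noiseSd > 0)
    f <- withSeed(seed, f + stats::rnorm(length(f), 0, noiseSd))
  new("ForceCurve", indentation = delta, force = f,
      contactOffset = contactOffset, valid = TRUE)
}

invalidForceCurve <- function(contactOffset = NA_real_) {
  new("ForceCurve", indentation = numeric(), force = numeric(),
      contactOffset = contactOffset, valid = FALSE)
}

#' Simulate an 8 x 8 force map at a measurement site
#'
#' Generates the \code{gridN^2} force-indentation curves of one measurement
#' site: curve (i, j) sits at the centre of grid cell (i, j) of a
#' \code{mapSide} x \code{mapSide} um area centred on \code{siteCenter}
#' (pitch \code{mapSide / gridN} = 1.25 um at the defaults). Each curve's
#' true E is the EM field sampled at its point, its contact offset is the
#' topology height there (plus measurement noise), and with probability
#' \code{dropoutProb} a curve is unrecoverable and marked invalid, mirroring
#' locations where the surface was beyond the cantilever retraction range.
#'
#' @param emField an \linkS4class{EMField}.
#' @param topology a \linkS4class{TopologyField} on the same grid.
#' @param siteCenter c(y, x) site centre in um from the field top-left corner.
#' @param config an \linkS4class{AcquisitionConfig}.
#' @param dropoutProb probability in [0, 1) that a curve is invalid.
#' @param forceNoiseSd per-sample force noise SD, nN.
#' @param offsetNoiseSd contact-offset measurement noise SD, um.
#' @param seed integer seed.
#' @return a list with \code{curves} (list of \linkS4class{ForceCurve} in
#'   row-major grid order), \code{siteCenter}, \code{pitch} and
#'   \code{trueEm} / \code{trueTopology} ground-truth grids.
#' @export
simulateForceMap <- function(emField, topology, siteCenter,
                             config = acquisitionConfig(), dropoutProb = 0,
                             forceNoiseSd = 0.01, offsetNoiseSd = 0.02,
                             seed = 1L) {
  if (dropoutProb < 0 || dropoutProb >= 1) stop("dropoutProb must be in [0, 1)")
  fieldExtent <- dim(emField@values) * emField@pixelSize
  half <- config@mapSide / 2
  if (any(siteCenter < half) || any(siteCenter > fieldExtent - half))
    stop(sprintf("site (%.2f, %.2f) um lies outside the field (%.2f x %.2f um)",
                 siteCenter[1], siteCenter[2], fieldExtent[1], fieldExtent[2]))
  n <- config@gridN
  pitch <- config@afmGridPitch
  offs <- (seq_len(n) - (n + 1) / 2) * pitch
  ys <- siteCenter[1] + offs
  xs <- siteCenter[2] + offs
  trueEm <- bilinearGrid(emField@values, emField@pixelSize, ys, xs)
  trueTopo <- bilinearGrid(topology@heights, topology@pixelSize, ys, xs)
  withSeed(seed, {
    drop <- matrix(stats::runif(n * n) < dropoutProb, n, n)
    offNoise <- matrix(stats::rnorm(n * n, 0, offsetNoiseSd), n, n)
    curves <- vector("list", n * n)
    idx <- 1L
    for (i in seq_len(n)) for (j in seq_len(n)) {   # row-major grid order
      curves[[idx]] <- if (drop[i, j]) invalidForceCurve() else
        simulateForceCurve(max(trueEm[i, j], 0), config, forceNoiseSd,
                           contactOffset = trueTopo[i, j] + offNoise[i, j],
                           seed = childSeed(seed, idx))
      idx <- idx + 1L
    }
    list(curves = curves, siteCenter = siteCenter, pitch = pitch,
         trueEm = trueEm, trueTopology = trueTopo)
  })
}

#' Synthetic cantilever template
#'
#' Renders a synthetic template image of the cantilever assembly at a given
#' magnification: a dark tapered cantilever body carrying the borosilicate
#' bead whose centre is the tissue contact (measurement) point, with an
#' opacity mask for compositing over tissue scenes. All magnifications view
#' the *same physical scene* (coordinates fixed in um around the bead), so a
#' high-magnification template is a genuine sub-view of a low-magnification
#' one and template chains can be registered across scales. Purely synthetic
#' stand-in for a photographed template.
#'
#' @param magnification objective magnification.
#' @param extentUm4x field extent c(height, width) in um *at 4x*; the extent
#'   at magnification m is \code{extentUm4x * 4 / m} (same pixel count at
#'   every magnification).
#' @param cameraPixel4x camera pixel size at 4x in um; pixel size at
#'   magnification m is \code{cameraPixel4x * 4 / m}.
#' @param beadRadiusUm bead radius in um.
#' @return a \linkS4class{CantileverTemplate}; its \code{measurementPoint} is
#'   the bead centre in template pixel coordinates.
#' @export
makeCantileverTemplate <- function(magnification = 4,
                                   extentUm4x = c(150, 120),
                                   cameraPixel4x = 1.625, beadRadiusUm = 5) {
  ps <- cameraPixel4x * 4 / magnification
  ext <- extentUm4x * 4 / magnification
  nr <- as.integer(round(ext[1] / ps))
  nc <- as.integer(round(ext[2] / ps))
  # scene coordinates (u, v) in um with the bead centre at the origin;
  # template top-left chosen so the bead sits at 62% height, centred
  tl <- c(-0.62 * ext[1], -0.5 * ext[2])
  U <- outer(tl[1] + (seq_len(nr) - 0.5) * ps, rep(1, nc))
  V <- outer(rep(1, nr), tl[2] + (seq_len(nc) - 0.5) * ps)
  # tapered body approaching the bead from the top
  halfw <- 2 + 0.35 * pmax(-U - 2, 0)
  body <- U <= -2 & abs(V) <= pmin(halfw, 30)
  bead <- U^2 + V^2 <= beadRadiusUm^2
  img <- matrix(0.55, nr, nc)
  img[body] <- 0.18
  img[bead] <- 0.08
  alpha <- matrix(0, nr, nc)
  alpha[body | bead] <- 0.95
  new("CantileverTemplate", image = img, alpha = alpha,
      measurementPoint = c(-tl[1] / ps + 0.5, -tl[2] / ps + 0.5),
      magnification = magnification)
}

#' Render a cantilever-occluded AFM field of view
#'
#' Crops the AFM camera's field of view out of the whole-sample image and
#' alpha-composites the cantilever template so that its known measurement
#' point lands on the requested site centre, emulating the occluded scene the
#' AFM camera records immediately before each measurement. The planted
#' geometry is returned for registration ground truth.
#'
#' @param wholeImage whole-sample \linkS4class{MicroscopyImage}.
#' @param siteCenter c(y, x) site centre in um on the whole-sample image.
#' @param template a \linkS4class{CantileverTemplate} at the image's
#'   magnification.
#' @param fovUm FOV extent c(height, width) in um (the AFM camera's 3.3 x
#'   2.5 mm sensor by default; clamped cohorts use smaller scenes).
#' @param noiseSd additional intensity noise added to the composited FOV.
#' @param seed integer seed.
#' @return a list: \code{fov} (\linkS4class{MicroscopyImage}),
#'   \code{fovOrigin} (um, top-left of the FOV on the whole image),
#'   \code{sitePx} (planted site centre in FOV pixels),
#'   \code{templateOrigin} (1-based top-left pixel of the template in the
#'   FOV) and \code{siteCenter} (the planted centre, um, on the whole image).
#' @export
renderAfmFov <- function(wholeImage, siteCenter, template,
                         fovUm = c(2500, 3300), noiseSd = 0.004, seed = 1L) {
  ps <- wholeImage@pixelSize
  imgDim <- dim(wholeImage@pixels)
  fovDim <- as.integer(round(fovUm / ps))
  if (any(dim(template@image) >= fovDim))
    stop("template must be smaller than the FOV")
  if (any(fovDim > imgDim))
    stop("FOV larger than the whole-sample image")
  # FOV centred on the site, clamped inside the image
  ctrPx <- siteCenter / ps
  tl <- round(ctrPx - fovDim / 2)
  tl <- pmin(pmax(tl, 0), imgDim - fovDim)
  fov <- wholeImage@pixels[(tl[1] + 1):(tl[1] + fovDim[1]),
                           (tl[2] + 1):(tl[2] + fovDim[2])]
  sitePx <- ctrPx - tl                # site centre in FOV pixel units
  # place template so its measurement point lies on the site centre
  mp <- template@measurementPoint
  t0 <- round(sitePx - mp) # 0-based top-left of template in FOV
  td <- dim(template@image)
  if (any(t0 < 0) || any(t0 + td > fovDim))
    stop(sprintf("site (%.1f, %.1f) um too close to the border for a full FOV + template",
                 siteCenter[1], siteCenter[2]))
  rows <- (t0[1] + 1):(t0[1] + td[1])
  cols <- (t0[2] + 1):(t0[2] + td[2])
  a <- template@alpha
  fov[rows, cols] <- (1 - a) * fov[rows, cols] + a * template@image
  if (noiseSd > 0)
    fov <- withSeed(seed, fov + matrix(stats::rnorm(length(fov), 0, noiseSd),
                                       nrow(fov), ncol(fov)))
  list(fov = new("MicroscopyImage", pixels = pmin(pmax(fov, 0), 1),
                 pixelSize = ps, magnification = wholeImage@magnification),
       fovOrigin = tl * ps, sitePx = sitePx, templateOrigin = t0 + 1,
       siteCenter = siteCenter)
}
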