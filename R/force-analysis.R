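#' Fit the Hertz spherical-indenter model to a force curve
#'
#' Estimates the elastic modulus by least squares on the approach segment.
#' Because the Hertz law \code{F = (4/3) * E / (1 - nu^2) * sqrt(R) * d^(3/2)}
#' is linear in E, the fit is a closed-form origin-constrained regression of
#' force against \code{d^(3/2)}:
#' \code{E = sum(F d^1.5) / sum(d^3) / C} with
#' \code{C = (4/3) sqrt(R) / (1 - nu^2)}. Invalid curves yield NaN (the
#' acquisition software's bookkeeping convention) rather than an error;
#' negative fitted values (possible under noise for very soft points) are
#' clamped to 0 with a warning.
#'
#' For measured (non-synthetic) curves with a force baseline before contact,
#' \code{contactThreshold} trims leading samples whose force stays below the
#' threshold (nN) before fitting; synthetic curves have exact contact at zero
#' indentation so the default 0 bypasses it.
#'
#' @param curve a \linkS4class{ForceCurve}.
#' @param config an \linkS4class{AcquisitionConfig}.
#' @param contactThreshold baseline force threshold in nN (0 = off).
#' @return fitted E in kPa (>= 0), or NaN for an invalid curve.
#' @export
fitHertzSphere <- function(curve, config = acquisitionConfig(),
                           contactThreshold = 0) {
  if (!curve@valid) return(NaN)
  d <- curve@indentation
  f <- curve@force
  if (contactThreshold > 0) {
    above <- which(f > contactThreshold)
    if (length(above)) {
      i0 <- above[1]
      d <- d[i0:length(d)] - d[i0]
      f <- f[i0:length(f)] - f[i0]
    }
  }
  if (length(d) < 5 || max(d) <= 0)
    stop("curve must have >= 5 samples and positive max indentation")
  C <- (4 / 3) * sqrt(config@beadRadius) / (1 - config@poissonRatio^2)
  x <- d^1.5
  E <- sum(f * x) / sum(x^2) / C
  if (is.nan(E)) E <- 0
  if (E < 0) {
    warning("negative fitted E clamped to 0")
    E <- 0
  }
  E
}

#' Process a set of force curves into a ForceMap
#'
#' Converts the \code{gridN^2} curves of one measurement site (row-major grid
#' order) into per-point elastic moduli and relative topology. EM comes from
#' \code{\link{fitHertzSphere}}; topology is each curve's axial contact-point
#' offset minus the map's median offset (heights are relative; the median is
#' the datum). Invalid curves propagate as NaN in both grids.
#'
#' @param curves list of \linkS4class{ForceCurve} in row-major grid order.
#' @param config an \linkS4class{AcquisitionConfig}.
#' @param siteId site identifier.
#' @param siteCenter optional site centre in um (NA until registered).
#' @return a \linkS4class{ForceMap}.
#' @export
processForceMap <- function(curves, config = acquisitionConfig(),
                            siteId = "site", siteCenter = c(NA_real_, NA_real_)) {
  n <- config@gridN
  if (length(curves) != n * n)
    stop(sprintf("expected %d curves (gridN^2), got %d", n * n, length(curves)))
  em <- matrix(NA_real_, n, n)
  topo <- matrix(NA_real_, n, n)
  for (k in seq_along(curves)) {
    cu <- curves[[k]]
    i <- (k - 1L) %/% n + 1L
    j <- (k - 1L) %% n + 1L
    em[i, j] <- fitHertzSphere(cu, config)
    topo[i, j] <- if (cu@valid) cu@contactOffset else NA_real_
  }
  topo <- topo - stats::median(topo, na.rm = TRUE)
  em[is.nan(em)] <- NA_real_
  new("ForceMap", em = em, topology = topo,
      siteCenter = as.numeric(siteCenter), pitch = config@afmGridPitch,
      siteId = siteId)
}

#' Write / read a ForceMap as CSV + JSON
#'
#' Serialises a processed force map as an \code{em.csv} / \code{topology.csv}
#' matrix pair plus a JSON metadata file (site id, centre, pitch).
#'
#' @param fm a \linkS4class{ForceMap}.
#' @param dir directory for the three files.
#' @return \code{writeForceMap} returns \code{dir} invisibly;
#'   \code{readForceMap} the \linkS4class{ForceMap}.
#' @export
writeForceMap <- function(fm, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(fm@em, file.path(dir, "em.csv"), row.names = FALSE)
  utils::write.csv(fm@topology, file.path(dir, "topology.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(siteId = fm@siteId, siteCenter = fm@siteCenter,
                            pitch = fm@pitch),
                       file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname writeForceMap
#' @export
readForceMap <- function(dir) {
  em <- as.matrix(utils::read.csv(file.path(dir, "em.csv")))
  topo <- as.matrix(utils::read.csv(file.path(dir, "topology.csv")))
  dimnames(em) <- dimnames(topo) <- NULL
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  ctr <- as.numeric(meta$siteCenter)
  if (length(ctr) != 2) ctr <- c(NA_real_, NA_real_)
  new("ForceMap", em = em, topology = topo, siteCenter = ctr,
      pitch = meta$pitch, siteId = meta$siteId)
}
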