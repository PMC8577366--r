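#' Generate a synthetic tissue cohort
#'
#' Builds a full synthetic study cohort: for each sample a ground-truth EM
#' field, a coupled topology field, a rendered unstained whole-sample image
#' and simulated force maps at randomly placed measurement sites.
#'
#' Between-sample biological heterogeneity is part of the emulation: each
#' sample's component means are shifted by one draw of
#' \code{N(0, shiftSd^2)} kPa and its component widths scaled by a lognormal
#' factor (sigma \code{sdScaleSigma}), reflecting patient-to-patient
#' variability of liver stiffness. Sections of the less common pathologies are
#' modelled as mixed tissue, as in real resection material where pathologist
#' labels are compounds: a "necrotic" sample is a blend of necrotic and
#' healthy tissue and a "fibrotic" sample a blend of fibrotic and tumour
#' tissue, with the dominant class occupying a fraction drawn uniformly from
#' \code{purity}. Blended samples carry compound labels (e.g.
#' \code{"necrotic/no_tumour"}).
#'
#' The default composition mirrors a 28-sample liver cohort dominated by
#' tumour and non-tumour sections with a minority of necrotic and fibrotic
#' ones; pass \code{nPerClass} for a balanced design.
#'
#' @param composition named integer vector of samples per class; default
#'   \code{c(no_tumour = 10, necrotic = 4, fibrotic = 2, tumour = 12)}.
#' @param nPerClass if given (>= 1), overrides \code{composition} with a
#'   balanced design over \code{classList}.
#' @param classList classes used with \code{nPerClass}.
#' @param seed integer seed; the cohort is fully reproducible given it.
#' @param fieldShape per-sample field size in pixels at \code{pixelSize}.
#' @param pixelSize field pixel size, um.
#' @param correlationLength spatial correlation length, um.
#' @param shiftSd between-sample SD of component-mean shifts, kPa.
#' @param sdScaleSigma lognormal sigma of the per-sample width scale.
#' @param purity range of the dominant-class fraction for blended samples.
#' @param sitesPerSample integer range of force-map sites per sample.
#' @param dropoutProb per-curve dropout probability.
#' @param what character vector of parts to generate: \code{"fields"} is
#'   always generated; add \code{"images"} and/or \code{"force"}.
#' @param config an \linkS4class{AcquisitionConfig}.
#' @param pure logical; TRUE disables blending (pure single-class samples).
#' @return a \linkS4class{TissueCohort}. Each element of
#'   \code{cohortSamples()} is a list with \code{sampleId}, \code{labels},
#'   \code{emField}, \code{topology}, and (when requested) \code{image},
#'   \code{mask} and \code{sites} (each site: \code{siteId},
#'   \code{siteCenter}, \code{curves}, \code{trueEm}, \code{trueTopology}).
#' @examples
#' co <- generateCohort(nPerClass = 1, classList = "no_tumour", seed = 1,
#'                      fieldShape = c(48, 48), what = "fields",
#'                      sitesPerSample = c(10, 12))
#' cohortRecords(co)
#' @export
generateCohort <- function(composition = c(no_tumour = 10, necrotic = 4,
                                           fibrotic = 2, tumour = 12),
                           nPerClass = NULL, classList = tissueClasses(),
                           seed = 1L, fieldShape = c(128L, 128L),
                           pixelSize = 1.25, correlationLength = 2,
                           shiftSd = 0.2, sdScaleSigma = 0.2,
                           purity = c(0.6, 0.85),
                           sitesPerSample = c(10L, 20L), dropoutProb = 0.02,
                           what = c("fields", "images", "force"),
                           config = acquisitionConfig(), pure = FALSE) {
  if (!is.null(nPerClass)) {
    if (length(classList) == 0) stop("class list must not be empty")
    if (nPerClass < 1) stop("nPerClass must be >= 1")
    composition <- stats::setNames(rep(as.integer(nPerClass),
                                       length(classList)), classList)
  }
  if (length(composition) == 0 || sum(composition) == 0)
    stop("class list must not be empty")
  bad <- setdiff(names(composition), tissueClasses())
  if (length(bad))
    stop("unknown tissue classes: ", paste(bad, collapse = ", "),
         "; valid classes: ", paste(tissueClasses(), collapse = ", "))
  partner <- c(no_tumour = NA, necrotic = "no_tumour",
               fibrotic = "tumour", tumour = NA)
  labs <- rep(names(composition), composition)
  nS <- length(labs)
  samples <- vector("list", nS)
  rec <- vector("list", nS)
  for (s in seq_len(nS)) {
    cl <- labs[s]
    sSeed <- childSeed(seed, s)
    draw <- withSeed(sSeed, list(
      shift = stats::rnorm(1, 0, shiftSd),
      scale = exp(stats::rnorm(1, 0, sdScaleSigma)),
      frac = stats::runif(1, purity[1], purity[2]),
      nSites = sample(seq.int(sitesPerSample[1], sitesPerSample[2]), 1)))
    p <- tissueClassParams(cl)
    labels <- cl
    if (!pure && !is.na(partner[[cl]])) {
      q <- tissueClassParams(partner[[cl]])
      p <- list(means = c(p$means, q$means), sds = c(p$sds, q$sds),
                weights = c(p$weights * draw$frac,
                            q$weights * (1 - draw$frac)))
      labels <- c(cl, partner[[cl]])
    }
    p$means <- pmax(p$means + draw$shift, 0.05)
    p$sds <- p$sds * draw$scale
    sampleId <- sprintf("S%03d", s)
    em <- generateEMField(paste(labels, collapse = "/"), fieldShape,
                          pixelSize, correlationLength, emParams = p,
                          seed = childSeed(sSeed, 1))
    topo <- generateTopologyField(em, seed = childSeed(sSeed, 2))
    smp <- list(sampleId = sampleId, labels = labels, emField = em,
                topology = topo, emParams = p)
    if ("images" %in% what) {
      mask <- defaultTissueMask(fieldShape)
      smp$mask <- mask
      smp$image <- renderUnstainedImage(em, topo, tissueMask = mask,
                                        cameraPixel = config@cameraPixel,
                                        seed = childSeed(sSeed, 3))
    }
    if ("force" %in% what) {
      extent <- fieldShape * pixelSize
      margin <- config@mapSide / 2 + 10
      centers <- withSeed(childSeed(sSeed, 4), {
        cbind(stats::runif(draw$nSites, margin, extent[1] - margin),
              stats::runif(draw$nSites, margin, extent[2] - margin))
      })
      smp$sites <- lapply(seq_len(draw$nSites), function(k) {
        fm <- simulateForceMap(em, topo, centers[k, ], config, dropoutProb,
                               seed = childSeed(sSeed, 100 + k))
        c(list(siteId = sprintf("%s_site%02d", sampleId, k)), fm)
      })
    }
    samples[[s]] <- smp
    rec[[s]] <- data.frame(sampleId = sampleId,
                           labels = paste(labels, collapse = "/"),
                           primaryClass = cl,
                           nSites = if ("force" %in% what) draw$nSites else 0L,
                           stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rec)
  names(samples) <- records$sampleId
  new("TissueCohort", samples = samples, records = records,
      seed = as.integer(seed))
}

#' Write / read a cohort as plain on-disk artifacts
#'
#' \code{writeCohort} serialises a cohort to a directory tree of standard
#' formats: a JSON cohort manifest, and per sample a single-channel TIFF of
#' the unstained image with a JSON metadata sidecar (pixel size,
#' magnification), ground-truth EM and topology CSV matrices, a JSON site
#' manifest and a long-format CSV of all force curves (columns
#' \code{site_id, row, col, indentation, force, valid}).
#' \code{readCohort} reads the tree back into the same list structure (force
#' curves are reconstructed as \linkS4class{ForceCurve} objects).
#'
#' @param cohort a \linkS4class{TissueCohort}.
#' @param dir output directory (created if needed).
#' @return \code{writeCohort} returns \code{dir} invisibly;
#'   \code{readCohort} returns a list with \code{records} and \code{samples}.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(seed = cohort@seed, records = cohort@records),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  for (smp in cohort@samples) {
    sd <- file.path(dir, smp$sampleId)
    dir.create(sd, showWarnings = FALSE)
    utils::write.csv(smp$emField@values, file.path(sd, "em_gt.csv"),
                     row.names = FALSE)
    utils::write.csv(smp$topology@heights, file.path(sd, "topology_gt.csv"),
                     row.names = FALSE)
    if (!is.null(smp$image)) {
      tiff::writeTIFF(smp$image@pixels, file.path(sd, "image.tif"),
                      bits.per.sample = 16L)
      jsonlite::write_json(
        list(pixelSize = smp$image@pixelSize,
             magnification = smp$image@magnification),
        file.path(sd, "image.json"), auto_unbox = TRUE, digits = NA)
    }
    if (!is.null(smp$sites)) {
      jsonlite::write_json(
        lapply(smp$sites, function(st)
          list(siteId = st$siteId, siteCenter = st$siteCenter,
               pitch = st$pitch)),
        file.path(sd, "sites.json"), auto_unbox = TRUE, digits = NA)
      rows <- lapply(smp$sites, function(st) {
        n <- sqrt(length(st$curves))
        do.call(rbind, lapply(seq_along(st$curves), function(k) {
          cu <- st$curves[[k]]
          i <- (k - 1L) %/% n + 1L
          j <- (k - 1L) %% n + 1L
          if (cu@valid)
            data.frame(site_id = st$siteId, row = i, col = j,
                       indentation = cu@indentation, force = cu@force,
                       contact_offset = cu@contactOffset, valid = TRUE)
          else
            data.frame(site_id = st$siteId, row = i, col = j,
                       indentation = NA_real_, force = NA_real_,
                       contact_offset = cu@contactOffset, valid = FALSE)
        }))
      })
      utils::write.csv(do.call(rbind, rows),
                       file.path(sd, "force_curves.csv"), row.names = FALSE)
    }
  }
  invisible(dir)
}

#' @rdname writeCohort
#' @export
readCohort <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  records <- as.data.frame(man$records)
  samples <- lapply(records$sampleId, function(sid) {
    sd <- file.path(dir, sid)
    out <- list(sampleId = sid,
                labels = strsplit(records$labels[records$sampleId == sid],
                                  "/", fixed = TRUE)[[1]])
    emv <- as.matrix(utils::read.csv(file.path(sd, "em_gt.csv")))
    dimnames(emv) <- NULL
    out$emGroundTruth <- emv
    imgf <- file.path(sd, "image.tif")
    if (file.exists(imgf)) {
      meta <- jsonlite::read_json(file.path(sd, "image.json"),
                                  simplifyVector = TRUE)
      out$image <- new("MicroscopyImage", pixels = tiff::readTIFF(imgf),
                       pixelSize = meta$pixelSize,
                       magnification = meta$magnification)
    }
    sitesf <- file.path(sd, "sites.json")
    if (file.exists(sitesf)) {
      sites <- jsonlite::read_json(sitesf, simplifyVector = TRUE,
                                   simplifyDataFrame = FALSE)
      curves <- utils::read.csv(file.path(sd, "force_curves.csv"))
      out$sites <- lapply(sites, function(st) {
        cc <- curves[curves$site_id == st$siteId, ]
        n <- max(cc$row)
        cl <- vector("list", n * n)
        for (i in seq_len(n)) for (j in seq_len(n)) {
          ck <- cc[cc$row == i & cc$col == j, ]
          k <- (i - 1L) * n + j
          cl[[k]] <- if (!any(ck$valid)) invalidForceCurve(ck$contact_offset[1])
            else new("ForceCurve", indentation = ck$indentation,
                     force = ck$force, contactOffset = ck$contact_offset[1],
                     valid = TRUE)
        }
        list(siteId = st$siteId, siteCenter = unlist(st$siteCenter),
             pitch = st$pitch, curves = cl)
      })
    }
    out
  })
  names(samples) <- records$sampleId
  list(records = records, samples = samples, seed = man$seed)
}
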