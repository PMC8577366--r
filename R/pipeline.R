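#' Pipeline configuration
#'
#' Builds the nested configuration driving \code{\link{runPipeline}}. The
#' single global \code{seed} fans out to per-stage seeds through a fixed
#' splitting rule (\code{stageSeed = (48271 * seed + 1000003 * stageIndex)
#' mod 2147483587}), so every stage is independently reproducible. The
#' \code{"desk"} profile bounds the simulation and training sizes so a full
#' run completes in minutes on one CPU; \code{"full"} scales the epoch count
#' and cohort sizes to the full-study settings (hours of compute).
#'
#' @param seed global integer seed.
#' @param outDir output directory for stage artifacts.
#' @param profile \code{"desk"} or \code{"full"}.
#' @param ... named overrides merged over the profile defaults (see the
#'   returned list for the available fields).
#' @return a config list.
#' @export
pipelineConfig <- function(seed = 1L, outDir = tempfile("nanoelast_"),
                           profile = c("desk", "full"), ...) {
  profile <- match.arg(profile)
  base <- list(
    seed = as.integer(seed), outDir = outDir, profile = profile,
    composition = c(no_tumour = 10, necrotic = 4, fibrotic = 2, tumour = 12),
    fieldShape = c(128L, 128L), sitesPerSample = c(10L, 20L),
    dropoutProb = 0.02, register = FALSE, fovUm = c(400, 400),
    baseFilters = 8L, epochs = 80L, batchSize = 16L, maxPairs = 200L,
    splitFraction = 0.8, stride = 32L, kMax = 6L, gapB = 100L)
  if (profile == "full") {
    base$fieldShape <- c(512L, 512L)
    base$baseFilters <- 64L
    base$epochs <- 10000L
    base$maxPairs <- Inf
    base$register <- TRUE
  }
  ov <- list(...)
  base[names(ov)] <- ov
  base
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file of \code{\link{pipelineConfig}} fields.
#' @return a config list.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipelineConfig, y)
}

stageSeed <- function(cfg, stage) {
  idx <- match(stage, c("simulate", "force", "register", "train",
                        "predict", "classify"))
  childSeed(cfg$seed, idx)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages simulate -> force-analyse -> register -> train ->
#' predict -> classify on a synthetic cohort, writing each stage's artifacts
#' under \code{cfg$outDir} together with a config echo carrying the config
#' hash, and returning the classification records. Stage failures raise
#' errors; artifacts of completed stages persist.
#'
#' @param cfg a \code{\link{pipelineConfig}}.
#' @param stages subset of stages to run (prerequisites must already have
#'   artifacts on disk or in the returned state).
#' @param verbose print per-stage timing.
#' @return (invisibly) a list with the classification \code{records}, the
#'   trained \code{generator}, the \code{summaries} and file paths.
#' @export
runPipeline <- function(cfg = pipelineConfig(),
                        stages = c("simulate", "force", "register", "train",
                                   "predict", "classify"),
                        verbose = TRUE) {
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  chars <- utf8ToInt(paste(deparse(cfg[order(names(cfg))]), collapse = ""))
  cfgHash <- sprintf("%08x", sum(chars * (seq_along(chars) %% 251 + 1)) %%
                       .Machine$integer.max)
  jsonlite::write_json(c(cfg[!vapply(cfg, is.function, logical(1))],
                         list(configHash = cfgHash)),
                       file.path(cfg$outDir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  tic <- function() Sys.time()
  say <- function(stage, t0) if (verbose)
    message(sprintf("[%s] done in %.1f s", stage,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  state <- list()

  if ("simulate" %in% stages) {
    t0 <- tic()
    cohort <- generateCohort(composition = cfg$composition,
                             seed = stageSeed(cfg, "simulate"),
                             fieldShape = cfg$fieldShape,
                             sitesPerSample = cfg$sitesPerSample,
                             dropoutProb = cfg$dropoutProb)
    writeCohort(cohort, file.path(cfg$outDir, "cohort"))
    state$cohort <- cohort
    say("simulate", t0)
  }

  if ("force" %in% stages) {
    t0 <- tic()
    if (is.null(state$cohort)) stop("missing artifact: cohort (run 'simulate' first)")
    fmDir <- file.path(cfg$outDir, "force_maps")
    state$forceMaps <- lapply(state$cohort@samples, function(smp)
      lapply(smp$sites, function(st) {
        fm <- processForceMap(st$curves, siteId = st$siteId,
                              siteCenter = st$siteCenter)
        writeForceMap(fm, file.path(fmDir, st$siteId))
        fm
      }))
    say("force", t0)
  }

  if ("register" %in% stages) {
    t0 <- tic()
    if (is.null(state$cohort)) stop("missing artifact: cohort (run 'simulate' first)")
    template <- if (cfg$register) makeCantileverTemplate(4) else NULL
    pairs <- cohortTrainingPairs(state$cohort, register = cfg$register,
                                 template4x = template, fovUm = cfg$fovUm)
    if (length(pairs) > cfg$maxPairs)
      pairs <- pairs[seq_len(cfg$maxPairs)]
    saveRDS(pairs, file.path(cfg$outDir, "pairs.rds"))
    jsonlite::write_json(
      lapply(pairs, function(p) list(sampleId = p@sampleId,
                                     siteId = p@siteId)),
      file.path(cfg$outDir, "pairs_index.json"), auto_unbox = TRUE)
    state$pairs <- pairs
    say("register", t0)
  }

  if ("train" %in% stages) {
    t0 <- tic()
    pf <- file.path(cfg$outDir, "pairs.rds")
    if (is.null(state$pairs)) {
      if (!file.exists(pf)) stop("missing artifact: pairs.rds (run 'register' first)")
      state$pairs <- readRDS(pf)
    }
    sp <- splitDataset(state$pairs, cfg$splitFraction,
                       seed = stageSeed(cfg, "train"))
    gc <- ganGeneratorConfig(baseFilters = cfg$baseFilters)
    tc <- ganTrainConfig(batchSize = cfg$batchSize, epochs = cfg$epochs,
                         seed = stageSeed(cfg, "train"))
    fit <- trainGan(sp$train, gc, tc, valPairs = sp$validation,
                    checkpointDir = file.path(cfg$outDir, "model"))
    utils::write.csv(fit$history, file.path(cfg$outDir, "history.csv"),
                     row.names = FALSE)
    state$generator <- fit$generator
    say("train", t0)
  }

  if ("predict" %in% stages) {
    t0 <- tic()
    if (is.null(state$generator)) {
      md <- file.path(cfg$outDir, "model")
      if (!file.exists(file.path(md, "generator.rds")))
        stop("missing artifact: model/generator.rds (run 'train' first)")
      state$generator <- loadGenerator(md)
    }
    if (is.null(state$cohort)) stop("missing artifact: cohort (run 'simulate' first)")
    pd <- file.path(cfg$outDir, "predictions")
    dir.create(pd, showWarnings = FALSE)
    state$predictions <- lapply(state$cohort@samples, function(smp) {
      pm <- predictWholeSample(smp$image, state$generator,
                               stride = cfg$stride, sampleId = smp$sampleId)
      tiff::writeTIFF(pm@em / 2, file.path(pd, paste0(smp$sampleId, "_em.tif")),
                      bits.per.sample = 16L)
      tiff::writeTIFF(pm@mask * 1, file.path(pd, paste0(smp$sampleId, "_mask.tif")),
                      bits.per.sample = 8L)
      pm
    })
    say("predict", t0)
  }

  if ("classify" %in% stages) {
    t0 <- tic()
    if (is.null(state$cohort)) stop("missing artifact: cohort (run 'simulate' first)")
    src <- if (!is.null(state$predictions)) state$predictions
      else lapply(state$cohort@samples, function(smp) smp$emField)
    summaries <- do.call(rbind, lapply(src, summarizeDistribution))
    records <- cbind(state$cohort@records, summaries)
    ks <- selectK(summaries[, c("mean", "sd", "skewness")], kMax = cfg$kMax,
                  B = cfg$gapB, seed = stageSeed(cfg, "classify"))
    model <- fitMixture(summaries[, c("mean", "sd", "skewness")], k = ks$k,
                        seed = stageSeed(cfg, "classify"))
    records <- assignAndName(model, records)
    records$correct <- mapply(function(p, l)
      any(strsplit(p, "/", fixed = TRUE)[[1]] %in%
            strsplit(l, "/", fixed = TRUE)[[1]]),
      records$predictedName, records$labels)
    utils::write.csv(records, file.path(cfg$outDir, "classification.csv"),
                     row.names = FALSE)
    state$records <- records
    state$k <- ks$k
    state$model <- model
    state$accuracy <- scoreAccuracy(records)
    say("classify", t0)
  }
  invisible(state)
}

#' Validate on-disk pipeline artifacts
#'
#' Checks the artifacts under a pipeline output directory against their
#' schemas: JSON files parse, TIFF images read, EM CSV matrices are
#' non-negative, EM/topology pairs agree in shape, prediction/mask TIFF
#' pairs agree in shape. Violations are reported per file.
#'
#' @param path pipeline output (or cohort) directory.
#' @return data.frame with columns \code{file} and \code{problem} (zero rows
#'   when everything checks out).
#' @export
validateFormats <- function(path) {
  bad <- list()
  note <- function(f, p) bad[[length(bad) + 1L]] <<- data.frame(file = f,
                                                                problem = p)
  for (jf in list.files(path, "\\.json$", recursive = TRUE,
                        full.names = TRUE)) {
    ok <- tryCatch({ jsonlite::read_json(jf); TRUE },
                   error = function(e) FALSE)
    if (!ok) note(jf, "invalid JSON")
  }
  for (tf in list.files(path, "\\.tif$", recursive = TRUE,
                        full.names = TRUE)) {
    ok <- tryCatch({ tiff::readTIFF(tf); TRUE }, error = function(e) FALSE)
    if (!ok) note(tf, "unreadable TIFF")
  }
  for (ef in list.files(path, "^em(_gt)?\\.csv$", recursive = TRUE,
                        full.names = TRUE)) {
    m <- tryCatch(as.matrix(utils::read.csv(ef)), error = function(e) NULL)
    if (is.null(m)) { note(ef, "unreadable CSV"); next }
    if (any(m[!is.na(m)] < 0)) note(ef, "negative EM value")
    tf <- file.path(dirname(ef), sub("^em", "topology", basename(ef)))
    if (file.exists(tf)) {
      tm <- tryCatch(as.matrix(utils::read.csv(tf)), error = function(e) NULL)
      if (!is.null(tm) && !identical(dim(m), dim(tm)))
        note(ef, "em/topology shape mismatch")
    }
  }
  pd <- file.path(path, "predictions")
  if (dir.exists(pd)) {
    for (ef in list.files(pd, "_em\\.tif$", full.names = TRUE)) {
      mf <- sub("_em\\.tif$", "_mask.tif", ef)
      if (!file.exists(mf)) { note(ef, "missing mask"); next }
      em <- tryCatch(tiff::readTIFF(ef), error = function(e) NULL)
      mk <- tryCatch(tiff::readTIFF(mf), error = function(e) NULL)
      if (!is.null(em) && !is.null(mk) && !identical(dim(em), dim(mk)))
        note(ef, "em/mask shape mismatch")
    }
  }
  if (length(bad)) do.call(rbind, bad)
  else data.frame(file = character(), problem = character())
}
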