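# Orchestration: simulate -> mask -> standardize -> decode -> perturb ->
# decompose, with one global seed deterministically deriving per-stage seeds,
# a JSON-serializable run configuration, and a machine-readable report plus a
# human-readable rendering.

#' Assemble a pipeline run configuration
#'
#' A plain, JSON-round-trippable container. `generator` and `ssflr` hold
#' argument lists for [generatorConfig()] and [ssflrConfig()]; per-stage
#' seeds are derived from the single global `seed` and override any seeds in
#' those lists.
#'
#' @param generator named list of [generatorConfig()] arguments.
#' @param maskPeaks path to a peak table TSV ([readPeakTable()]), or NULL to
#'   analyze the full grid.
#' @param maskRadius sphere radius in mm for [buildMaskFromPeaks()].
#' @param rfe list: `use` (logical), `floorSize`, `halving`.
#' @param perturb list: `schemes` (character subset of jackknife/bootstrap/
#'   split_half), `iterations` (count for bootstrap/split-half), `useRFE`.
#' @param ssflr named list of [ssflrConfig()] arguments, or NULL to skip the
#'   decomposition stage.
#' @param byTrial aggregate test predictions per trial (majority vote).
#' @param seed global seed.
#' @return a list of class `"RunConfig"`.
#' @export
runConfig <- function(generator = list(), maskPeaks = NULL, maskRadius = 15,
                      rfe = list(use = TRUE, floorSize = 16, halving = 0.5),
                      perturb = list(schemes = character(), iterations = 100,
                                     useRFE = FALSE),
                      ssflr = list(), byTrial = FALSE, seed = 1L) {
  cfg <- list(
    generator = generator,
    maskPeaks = maskPeaks,
    maskRadius = as.numeric(maskRadius),
    rfe = list(use = isTRUE(rfe$use %||% TRUE),
               floorSize = as.integer(rfe$floorSize %||% 16L),
               halving = as.numeric(rfe$halving %||% 0.5)),
    perturb = list(schemes = as.character(perturb$schemes %||% character()),
                   iterations = as.integer(perturb$iterations %||% 100L),
                   useRFE = isTRUE(perturb$useRFE %||% FALSE)),
    ssflr = ssflr,
    byTrial = isTRUE(byTrial),
    seed = as.integer(seed))
  class(cfg) <- c("RunConfig", "list")
  cfg
}

#' Write / read a run configuration as JSON
#'
#' The write-read round trip reproduces the configuration exactly.
#'
#' @param config a [runConfig()] list.
#' @param path JSON file path.
#' @return `writeRunConfig`: `path` invisibly; `readRunConfig`: the
#'   configuration.
#' @export
writeRunConfig <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(runConfig, raw)
}

#' Run the full analysis pipeline
#'
#' Stages, each with a seed derived from the global seed: (1) build the
#' search-space mask from the peak table, if configured; (2) generate ground
#' truth and simulate the trial-wise dataset (component blobs are placed
#' inside the mask so the search space contains the signal); (3) restrict
#' features to the mask; (4) cross-modal decoding with train-fitted
#' standardization and optional RFE; (5) the configured perturbation schemes;
#' (6) predictive pattern decomposition. Writes `report.json`, the component
#' volumes and the contribution table under `outdir` when given.
#'
#' @param config a [runConfig()] list.
#' @param outdir output directory, or NULL for an in-memory report only.
#' @return a list of class `"RunReport"`.
#' @export
runPipeline <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  stage <- function(nm) stageSeed(config$seed, nm)
  log <- function(...) message(format(Sys.time(), "%H:%M:%S "), ...)

  genArgs <- config$generator
  genArgs$seed <- stage("generator")
  genCfg <- do.call(generatorConfig, genArgs)
  grid <- mniGrid(genCfg@gridShape)

  mask <- NULL
  if (!is.null(config$maskPeaks)) {
    log("stage mask: building search space from ", config$maskPeaks)
    peaks <- readPeakTable(config$maskPeaks)
    mask <- buildMaskFromPeaks(peaks, config$maskRadius, grid)
  }

  log("stage simulate: ", genCfg@nSubjects, " subjects x ",
      genCfg@trialsPerSubject, " trials x ", genCfg@mapsPerTrial, " maps")
  truth <- makeGroundTruth(genCfg, mask)
  ds <- simulateDataset(genCfg, truth)
  dsA <- if (is.null(mask)) ds else ds[as.vector(mask@data), ]

  log("stage decode: cross-modal generalization on ", nVoxels(dsA),
      " voxels")
  parts <- splitByModality(dsA)
  decode <- crossModalGeneralize(parts$train, parts$test,
    useRFE = config$rfe$use, halving = config$rfe$halving,
    floorSize = config$rfe$floorSize, byTrial = config$byTrial,
    seed = stage("decode"))

  perturbs <- list()
  for (sc in config$perturb$schemes) {
    log("stage perturb: ", sc)
    perturbs[[sc]] <- perturbationSuite(dsA, sc,
      nIterations = if (sc == "jackknife") NULL else config$perturb$iterations,
      seed = stage(paste0("perturb_", sc)),
      useRFE = config$perturb$useRFE, byTrial = config$byTrial)
  }

  decomp <- NULL
  decompFiles <- character()
  if (!is.null(config$ssflr)) {
    ssArgs <- config$ssflr
    ssArgs$seed <- stage("ssflr")
    ssCfg <- do.call(ssflrConfig, ssArgs)
    log("stage decompose: k = ", ssCfg@nComponents, ", ",
        ssCfg@maxEpochs, " epochs")
    fit <- fitSSFLR(dsA, config = ssCfg)
    decomp <- fit
    if (!is.null(outdir) && !is.null(mask))
      decompFiles <- exportComponentMaps(fit$report, mask,
                                         file.path(outdir, "components"))
  }

  report <- list(
    decoding = list(
      n_correct = decode@nCorrect, n_total = decode@nTotal,
      accuracy = decode@accuracy, p_value = decode@pValue,
      chance = decode@chance,
      n_selected = sum(decode@selectedFeatures),
      rfe_sizes = if (is.null(decode@rfe)) NULL else decode@rfe@sizes),
    perturbations = lapply(perturbs, function(p) list(
      scheme = p@scheme, n_iterations = p@nIterations,
      mean_accuracy = p@meanAccuracy, sd_accuracy = p@sdAccuracy,
      mean_p = p@meanP, sd_p = p@sdP)),
    decomposition = if (is.null(decomp)) NULL else list(
      k = nrow(decomp$report@componentMaps),
      contributions = decomp$report@contributions,
      files = decompFiles),
    config = unclass(config),
    version = as.character(utils::packageVersion("CrossDecode")),
    seed = config$seed)
  attr(report, "objects") <- list(decode = decode, perturbs = perturbs,
                                  decomposition = decomp, mask = mask,
                                  truth = truth)
  class(report) <- c("RunReport", "list")

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    rep2 <- report
    if (!is.null(rep2$decomposition))
      rep2$decomposition$contributions <-
        as.data.frame(rep2$decomposition$contributions)
    jsonlite::write_json(unclass(rep2), file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE, force = TRUE)
  }
  report
}

#' Render a run report as human-readable text
#'
#' One decoding table, one 4 x k contribution table, the perturbation
#' summaries ("not run" when absent) and a file inventory with existence
#' checks. Pure formatting: nothing is recomputed or mutated.
#'
#' @param report a `"RunReport"` from [runPipeline()].
#' @return the rendered lines, invisibly; printed to the console.
#' @export
renderReport <- function(report) {
  stopifnot(inherits(report, "RunReport"))
  ln <- character()
  add <- function(...) ln <<- c(ln, paste0(...))
  d <- report$decoding
  add("== Cross-modal decoding ==")
  add(sprintf("  accuracy : %.2f%% (%d/%d, chance %.0f%%)",
              100 * d$accuracy, d$n_correct, d$n_total, 100 * d$chance))
  add(sprintf("  binomial p: %.3g", d$p_value))
  if (!is.null(d$rfe_sizes))
    add("  RFE sizes: ", paste(d$rfe_sizes, collapse = " -> "),
        sprintf(" (used %d features)", d$n_selected))
  add("")
  add("== Perturbation analyses ==")
  if (length(report$perturbations) == 0L) {
    add("  not run")
  } else {
    for (p in report$perturbations)
      add(sprintf("  %-10s: %d iterations, accuracy %.2f +/- %.2f%%, p %.3g +/- %.3g",
                  p$scheme, p$n_iterations, 100 * p$mean_accuracy,
                  100 * p$sd_accuracy, p$mean_p, p$sd_p))
  }
  add("")
  add("== Predictive pattern decomposition ==")
  if (is.null(report$decomposition)) {
    add("  not run")
  } else {
    add("  components: ", report$decomposition$k)
    cm <- report$decomposition$contributions
    cm <- if (is.data.frame(cm)) as.matrix(cm) else cm
    tab <- utils::capture.output(print(round(cm, 3)))
    ln <- c(ln, paste0("  ", tab))
    if (length(report$decomposition$files)) {
      add("  files:")
      for (f in report$decomposition$files)
        add("    ", f, if (file.exists(f)) "" else "  [missing]")
    }
  }
  add("")
  add("seed ", report$seed, ", CrossDecode ", report$version)
  cat(paste(ln, collapse = "\n"), "\n")
  invisible(ln)
}
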