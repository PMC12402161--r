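# Orchestration: a serializable run configuration, stage execution in
# dependency order, and per-stage output manifests. Identical config and
# seed give identical outputs for every deterministic stage.

#' Default run configuration
#'
#' All stage parameters with their standard defaults: IQR multiplier 1.5,
#' PCA variance retained 0.97, DEG cutoffs p 0.01 / |log2FC| 0.6, frame
#' interval 2 min over 90 min, minimum 20 cells per deformation summary.
#'
#' @param stages stages to run, any of `"transit"`, `"plate"`,
#'   `"profile"`, `"calcium"`, `"permeability"`, `"spheres"`, `"deg"`.
#' @param seed global RNG seed.
#' @param outDir output directory.
#' @return A nested list (class `RunConfig`), serializable to YAML.
#' @export
defaultRunConfig <- function(stages = c("transit", "plate", "profile"),
                             seed = 1L, outDir = tempfile("cellsqueeze_run_")) {
  structure(list(
    stages = stages, seed = as.integer(seed), outDir = outDir,
    transit = list(nCells = 20, minN = 20),
    plate = list(nWells = 4, cellsPerWell = 20, kIQR = 1.5),
    profile = list(varianceRetained = 0.97, bhFamily = "per-feature"),
    calcium = list(baseline = 100,
                   amplitudes = c(CC_30 = 1.0, CC_20 = 1.05,
                                  CC_10 = 1.4, CC_5 = 1.8)),
    permeability = list(pTrue = 1e-5, sOverV = 2, iVessel = 1000,
                        duration = 90, frameInterval = 2, fitFrames = 10),
    spheres = list(initialArea = 1000, growthRate = 500, days = 7),
    deg = list(input = NULL, pCut = 0.01, lfcCut = 0.6)
  ), class = "RunConfig")
}

#' Load a run configuration from YAML
#' @param path YAML file path; keys override the defaults.
#' @return A `RunConfig` list.
#' @export
readRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- defaultRunConfig()
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(cfg[[k]]))
      cfg[[k]][names(user[[k]])] <- user[[k]]
    else cfg[[k]] <- user[[k]]
  }
  class(cfg) <- "RunConfig"
  cfg
}

validateRunConfig <- function(config) {
  known <- names(defaultRunConfig())
  bad <- setdiff(names(config), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  allowed <- c("transit", "plate", "profile", "calcium", "permeability",
               "spheres", "deg")
  badStage <- setdiff(config$stages, allowed)
  if (length(badStage))
    stop("unknown stage(s): ", paste(badStage, collapse = ", "))
  if (!is.numeric(config$seed) || length(config$seed) != 1L)
    stop("config key 'seed' must be a single integer")
  invisible(TRUE)
}

writeManifest <- function(outDir, stage, params, seed, outputs) {
  man <- list(stage = stage, seed = seed, parameters = params,
              outputs = outputs,
              package = as.character(packageVersion("CellSqueeze")))
  jsonlite::write_json(man, file.path(outDir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

writeCSV <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  path
}

#' Run the analysis pipeline from a configuration
#'
#' Executes the requested stages in dependency order and writes each
#' stage's CSV outputs and a JSON manifest (parameters, seed, package
#' version) into the configured output directory, together with the
#' effective configuration. The `profile` stage consumes the single-cell
#' features produced by the `plate` stage of the same run and errors if
#' that stage was not requested.
#'
#' @param config a `RunConfig` list ([defaultRunConfig()] /
#'   [readRunConfig()]) or a YAML file path.
#' @return Invisibly, a named list of the per-stage result objects; side
#'   effect: files under `config$outDir`.
#' @export
runPipeline <- function(config = defaultRunConfig()) {
  if (is.character(config)) config <- readRunConfig(config)
  validateRunConfig(config)
  outDir <- config$outDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(unclass(config), file.path(outDir, "run_config.yaml"))
  seed <- as.integer(config$seed)
  results <- list()

  if ("transit" %in% config$stages) {
    geom <- deviceGeometry()
    params <- squeezeModelParams(seed = seed)
    sim <- generateTransitSequence(geom, params, config$transit$nCells)
    shapes <- transitMorphometrics(sim$stacks, geom)
    summ <- deformationSummary(shapes, minN = config$transit$minN)
    summ <- summ[summ$region != "BASELINE", , drop = FALSE]
    o1 <- writeCSV(shapes, file.path(outDir, "transit_shapes.csv"))
    o2 <- writeCSV(summ, file.path(outDir, "deformation_summary.csv"))
    writeManifest(outDir, "transit", config$transit, seed, c(o1, o2))
    results$transit <- list(shapes = shapes, summary = summ)
  }

  if ("plate" %in% config$stages) {
    spec <- plateSpec(nWells = config$plate$nWells,
                      cellsPerWell = config$plate$cellsPerWell, seed = seed)
    plate <- generateIFPlate(spec)
    feats <- lapply(seq_along(plate$wells), function(w) {
      st <- plate$wells[[w]]
      nuc <- segmentNuclei(st, channel = "DAPI")
      cells <- segmentCells(st, nuc, channel = "ACTIN")
      cyto <- deriveCytoplasm(cells, nuc)
      f <- extractFeatures(cells, channels = st, nuclei = nuc,
                           cytoplasm = cyto)
      if (nrow(f) == 0) return(NULL)
      f$well <- w
      f$condition <- spec$conditions[w]
      f$timepoint <- spec$timepoint
      f
    })
    feats <- do.call(rbind, feats)
    o <- writeCSV(feats, file.path(outDir, "single_cell_features.csv"))
    writeManifest(outDir, "plate", config$plate, seed, o)
    results$plate <- list(features = feats, truth = plate$truth)
  }

  if ("profile" %in% config$stages) {
    if (is.null(results$plate))
      stop("stage 'profile' requires the output of stage 'plate'; ",
           "add \"plate\" to config$stages")
    feats <- results$plate$features
    feats <- feats[!feats$qc_border & !feats$qc_empty_cytoplasm, ,
                   drop = FALSE]
    markerCols <- grep("^mean_.*_nucleus$", names(feats), value = TRUE)
    markers <- setdiff(sub("^mean_(.*)_nucleus$", "\\1", markerCols),
                       c("DAPI", "ACTIN"))
    for (m in markers)
      feats[[paste0("nc_", m)]] <- ncRatio(
        feats[[paste0("mean_", m, "_nucleus")]],
        feats[[paste0("mean_", m, "_cytoplasm")]])
    featCols <- c(paste0("mean_", markers, "_nucleus"),
                  paste0("mean_", markers, "_cytoplasm"),
                  paste0("nc_", markers))
    filt <- iqrOutlierFilter(feats, features = featCols,
                             k = config$plate$kIQR)
    comp <- compareGroups(filt$table, features = featCols,
                          bhFamily = config$profile$bhFamily)
    o1 <- writeCSV(filt$table, file.path(outDir, "profile_filtered.csv"))
    o2 <- writeCSV(comp, file.path(outDir, "profile_comparisons.csv"))
    writeManifest(outDir, "profile", config$profile, seed, c(o1, o2))
    results$profile <- list(filtered = filt, comparisons = comp)
  }

  if ("calcium" %in% config$stages) {
    sim <- generateCalciumSeries(baseline = config$calcium$baseline,
                                 regionAmplitudes = unlist(config$calcium$amplitudes),
                                 seed = seed)
    regions <- unique(sim$truth$region)
    fc <- vapply(regions, function(r)
      calciumFoldChange(sim$traces[[1]], responseWindow = r), numeric(1))
    out <- data.frame(region = regions, fold_change = fc)
    o <- writeCSV(out, file.path(outDir, "calcium_fold_change.csv"))
    writeManifest(outDir, "calcium", config$calcium, seed, o)
    results$calcium <- out
  }

  if ("permeability" %in% config$stages) {
    p <- config$permeability
    tr <- generatePermeabilitySeries(p$pTrue, p$sOverV, p$iVessel,
                                     p$duration, p$frameInterval, seed = seed)
    rec <- estimatePermeability(tr, iVessel = p$iVessel, sOverV = p$sOverV,
                                fitFrames = p$fitFrames)
    out <- data.frame(P_cm_per_s = rec$P, slope = rec$slope,
                      r_squared = rec$r_squared)
    o <- writeCSV(out, file.path(outDir, "permeability.csv"))
    writeManifest(outDir, "permeability", p, seed, o)
    results$permeability <- rec
  }

  if ("spheres" %in% config$stages) {
    s <- config$spheres
    sim <- generateTumorsphereSeries(s$initialArea, s$growthRate, s$days,
                                     seed = seed)
    track <- sphereTrack(sim$stack)
    fit <- fitGrowth(track)
    o <- writeCSV(track, file.path(outDir, "sphere_track.csv"))
    writeManifest(outDir, "spheres", s, seed, o)
    results$spheres <- list(track = track, fit = fit)
  }

  if ("deg" %in% config$stages) {
    if (is.null(config$deg$input))
      stop("stage 'deg' requires config$deg$input (CSV with gene, logFC, pvalue)")
    tab <- read.csv(config$deg$input)
    cls <- classifyDEG(tab, pCut = config$deg$pCut,
                       lfcCut = config$deg$lfcCut)
    o <- writeCSV(cls, file.path(outDir, "deg_labels.csv"))
    writeManifest(outDir, "deg", config$deg, seed, o)
    results$deg <- cls
  }

  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
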