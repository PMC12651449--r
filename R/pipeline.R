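#' Configure an end-to-end synthetic experiment
#'
#' Bundles everything [runPipeline()] needs: the simulation configuration,
#' the split fraction, which band selectors and model backends to run, the
#' cube size and the global seed from which every stochastic stage derives
#' its own deterministic sub-seed.
#'
#' @param sim a [SimConfig-class].
#' @param calibrationFraction SPXY calibration fraction (default 0.8).
#' @param selectors band selectors to run, among `"spa"`, `"cars"`,
#'   `"rfrog"`.
#' @param models backends to train, among `"plsr"`, `"rf"`, `"cnn"`.
#' @param cubeSize spatial side of the simulated cubes (default 64).
#' @param fullSpectrumBaseline also train a full-spectrum network baseline.
#' @param cnnEpochs,carsRuns,rfrogIterations stage budgets.
#' @param outDir optional output directory for CSV/JSON/PNG artifacts.
#' @param seed global integer seed.
#' @return a list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(sim = simConfig(), calibrationFraction = 0.8,
                           selectors = c("spa", "cars", "rfrog"),
                           models = c("plsr", "rf", "cnn"),
                           cubeSize = 64L, fullSpectrumBaseline = TRUE,
                           cnnEpochs = 200L, carsRuns = 50L,
                           rfrogIterations = 1000L, outDir = NULL,
                           seed = 1L) {
    structure(list(sim = sim, calibrationFraction = calibrationFraction,
                   selectors = match.arg(selectors, several.ok = TRUE),
                   models = match.arg(models, several.ok = TRUE),
                   cubeSize = as.integer(cubeSize),
                   fullSpectrumBaseline = fullSpectrumBaseline,
                   cnnEpochs = as.integer(cnnEpochs),
                   carsRuns = as.integer(carsRuns),
                   rfrogIterations = as.integer(rfrogIterations),
                   outDir = outDir, seed = as.integer(seed)),
              class = "PipelineConfig")
}

# Mean ROI spectra for every fruit of a quality table: simulate a cube,
# correct it, place the ROI automatically and average. Cubes are processed
# one at a time to keep memory flat. Returns the n x p spectra matrix.
tableSpectra <- function(table, axis, sim, cubeSize, seed,
                         keepCubes = integer(0)) {
    n <- nrow(table)
    X <- matrix(NA_real_, n, nBands(axis))
    kept <- list()
    for (i in seq_len(n)) {
        cb <- simulateCube(table[i, ], axis, sim, height = cubeSize,
                           width = cubeSize,
                           seed = deriveSeed(seed, paste0("cube", i)))
        corr <- radiometricCorrect(cb$raw, cb$refs)
        r <- autoROI(corr)
        X[i, ] <- meanSpectrum(corr, r)
        if (i %in% keepCubes) kept[[as.character(i)]] <- corr
    }
    list(X = X, cubes = kept)
}

#' Run the full synthetic study pipeline
#'
#' Simulate a shelf-life experiment, extract mean ROI spectra from
#' white/dark-corrected cubes, build the composite quality index (with its
#' adequacy diagnostics and loading-based parameter selection reported),
#' partition by SPXY, select characteristic bands, train the requested
#' model grid plus an optional full-spectrum network baseline, evaluate all
#' models on both sides of the split, and predict day-0/day-9 pixel maps on
#' a shared colour scale. Every stochastic stage derives its seed from the
#' global one, so identical configurations yield identical bundles.
#'
#' @param config a `PipelineConfig` from [pipelineConfig()].
#' @return a list: `table` (quality table with `kcqi`), `dataset`,
#'   `factorModel`, `selection`, `bands` (named [BandSubset-class] list),
#'   `fits` (named [FitResult-class] list), `report` (one row per
#'   model x selector with calibration/prediction metrics), `maps`
#'   (day-0/day-9 [KCQIMap-class]s) and `provenance`.
#' @export
runPipeline <- function(config) {
    sim <- config$sim
    seed <- config$seed
    axis <- spectralAxis()
    table <- simulateQualityTable(sim, seed = deriveSeed(seed, "table"))
    table <- addKCQI(table)

    # representative day-0 and day-9 fruit for the maps
    mapIdx <- c(which(table$day == min(table$day))[1],
                which(table$day == max(table$day))[1])
    sp <- tableSpectra(table, axis, sim, config$cubeSize, seed,
                       keepCubes = mapIdx)

    fm <- factorAnalysis(table)
    sel <- selectParameters(fm)

    ds <- spectralDataset(sp$X, table$kcqi, axis)
    ds <- spxySplit(ds, config$calibrationFraction)

    bands <- list()
    for (m in config$selectors)
        bands[[m]] <- switch(m,
            spa = spaSelect(ds),
            cars = carsSelect(ds, nRuns = config$carsRuns,
                              seed = deriveSeed(seed, "cars")),
            rfrog = rfrogSelect(ds, nIterations = config$rfrogIterations,
                                seed = deriveSeed(seed, "rfrog")))

    fitOne <- function(kind, bb, tag) {
        f <- switch(kind,
            plsr = fitPLSR(ds, bb),
            rf = fitRF(ds, bb, seed = deriveSeed(seed, paste0("rf.", tag))),
            cnn = fitCNN1D(ds, bb, epochs = config$cnnEpochs,
                           seed = deriveSeed(seed, paste0("cnn.", tag))))
        evaluateModel(evaluateModel(f, ds, "calibration"), ds, "prediction")
    }
    fits <- list()
    rows <- list()
    for (m in names(bands)) for (k in config$models) {
        tag <- paste(m, k, sep = "-")
        fits[[tag]] <- fitOne(k, bands[[m]], tag)
        rows[[tag]] <- data.frame(
            selector = m, model = k, nBands = length(bands[[m]]@indices),
            rc2 = fits[[tag]]@calibration$r2,
            rmsec = fits[[tag]]@calibration$rmse,
            rp2 = fits[[tag]]@prediction$r2,
            rmsep = fits[[tag]]@prediction$rmse,
            rpd = fits[[tag]]@prediction$rpd)
    }
    if (isTRUE(config$fullSpectrumBaseline) && "cnn" %in% config$models) {
        tag <- "full-cnn"
        fits[[tag]] <- fitOne("cnn", fullBands(ds), tag)
        rows[[tag]] <- data.frame(
            selector = "full", model = "cnn", nBands = nBands(axis),
            rc2 = fits[[tag]]@calibration$r2,
            rmsec = fits[[tag]]@calibration$rmse,
            rp2 = fits[[tag]]@prediction$r2,
            rmsep = fits[[tag]]@prediction$rmse,
            rpd = fits[[tag]]@prediction$rpd)
    }
    report <- do.call(rbind, rows)
    rownames(report) <- NULL

    maps <- list()
    if (length(fits)) {
        bestTag <- names(fits)[which.max(vapply(fits, function(f)
            f@prediction$r2, numeric(1)))]
        rawMaps <- lapply(sp$cubes, predictMap, model = fits[[bestTag]])
        rng <- range(unlist(lapply(rawMaps, function(m) m@values[m@mask])))
        maps <- lapply(sp$cubes, predictMap, model = fits[[bestTag]],
                       scaleRange = rng)
        names(maps) <- c("day0", "day9")[seq_along(maps)]
    }

    prov <- list(seed = seed, nFruits = nrow(table),
                 configHash = digestConfig(config),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    bundle <- list(table = table, dataset = ds, factorModel = fm,
                   selection = sel, bands = bands, fits = fits,
                   report = report, maps = maps, provenance = prov)
    if (!is.null(config$outDir)) writeBundle(bundle, config)
    bundle
}

# Stable short hash of the configuration (provenance only).
digestConfig <- function(config) {
    cfg <- config
    cfg$outDir <- NULL
    txt <- paste(utils::capture.output(utils::str(cfg, digits.d = 12)),
                 collapse = "\n")
    sum(utf8ToInt(txt) * seq_len(nchar(txt))) %% 1e9
}

writeBundle <- function(bundle, config) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    keep <- !startsWith(names(bundle$table), ".")
    utils::write.csv(bundle$table[keep], file.path(config$outDir,
                                                   "quality_table.csv"),
                     row.names = FALSE)
    utils::write.csv(bundle$report, file.path(config$outDir, "report.csv"),
                     row.names = FALSE)
    fm <- bundle$factorModel
    jsonlite::write_json(
        list(kmo = fm@kmo, bartlett = as.list(fm@bartlett),
             eigenvalues = fm@eigenvalues,
             cumulativeVariance = fm@cumulativeVariance,
             loadings = as.data.frame(fm@loadings),
             selected = bundle$selection$selected,
             bands = lapply(bundle$bands, function(b)
                 list(method = b@method, indices = b@indices,
                      wavelengths = b@wavelengths)),
             provenance = bundle$provenance),
        file.path(config$outDir, "summary.json"), auto_unbox = TRUE,
        digits = NA)
    for (nm in names(bundle$maps))
        renderMap(bundle$maps[[nm]],
                  file.path(config$outDir, paste0("map_", nm, ".png")))
    invisible(config$outDir)
}
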