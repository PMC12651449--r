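# Shared fixtures, all generated in code.

# Default config is expensive-ish to build (feature-noise calibration), so
# cache one per session.
defaultCfg <- local({
    cfg <- NULL
    function() {
        if (is.null(cfg)) cfg <<- simConfig()
        cfg
    }
})

# Small quality table + per-fruit spectra (no cubes), as a split dataset.
makeDataset <- function(cfg = defaultCfg(), seed = 42, nPerGroup = NULL,
                        split = TRUE) {
    tab <- addKCQI(simulateQualityTable(cfg, nPerGroup = nPerGroup,
                                        seed = seed))
    ax <- spectralAxis()
    X <- t(vapply(seq_len(nrow(tab)), function(i)
        simulateSpectrum(tab[i, ], ax, cfg, seed = seed * 1000 + i),
        numeric(nBands(ax))))
    ds <- spectralDataset(X, tab$kcqi, ax)
    if (split) ds <- spxySplit(ds)
    list(table = tab, ds = ds, axis = ax)
}

# Planted-signal benchmark: y depends on exactly `planted` known bands.
makePlanted <- function(n = 120, p = 60, planted = c(7, 19, 31, 44, 55),
                        noiseSD = 0.05, seed = 1) {
    set.seed(seed)
    X <- matrix(rnorm(n * p), n, p)
    y <- rowSums(X[, planted, drop = FALSE]) + rnorm(n, 0, noiseSD)
    ds <- spectralDataset(X, y, spectralAxis(wavelengths = seq_len(p)))
    ds <- spxySplit(ds)
    list(ds = ds, planted = planted)
}

# A tiny constant-valued corrected cube.
constantCube <- function(value = 0.5, h = 8, w = 8, b = 6) {
    hyperCube(array(value, c(h, w, b)),
              spectralAxis(wavelengths = seq_len(b)), kind = "corrected")
}

# Quality record with round numbers for exact index arithmetic.
unitRecord <- function(firmness = 1, L = 1, b = 1, chroma = 1, ssc = 1000) {
    data.frame(firmness = firmness, L = L, b = b, chroma = chroma, ssc = ssc)
}
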