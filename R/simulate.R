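# Core generative draw shared by simulateQualityTable() and the internal
# feature-noise calibration. Consumes the ambient RNG stream; callers are
# responsible for seeding. `nTotal` (if given) overrides the per-group size
# and assigns cultivar/day labels round-robin.
drawQuality <- function(config, nTotal = NULL) {
    if (is.null(nTotal)) {
        grid <- expand.grid(idx = seq_len(config@nPerGroup),
                            day = config@days, cultivar = config@cultivars,
                            stringsAsFactors = FALSE)
        day <- grid$day; cultivar <- grid$cultivar
    } else {
        cells <- expand.grid(day = config@days, cultivar = config@cultivars,
                             stringsAsFactors = FALSE)
        i <- rep_len(seq_len(nrow(cells)), nTotal)
        day <- cells$day[i]; cultivar <- cells$cultivar[i]
    }
    n <- length(day)
    theta <- day / max(config@days, 1) + stats::rnorm(n, 0, config@thetaSD)
    u <- stats::rnorm(n)
    tr <- config@trajectories
    slopes <- tr[, 2] - tr[, 1]
    s <- qualityNoiseSDs(config)
    cc <- c(ssc = 0, firmness = unname(config@coupling["firmness"]),
            L = 0, a = unname(config@coupling["a"]), b = 0)
    val <- sapply(rownames(tr), function(v)
        tr[v, 1] + slopes[v] * theta + cc[v] * u + stats::rnorm(n, 0, s[v]))
    # physical floors: the Gaussian tails may otherwise cross zero, which has
    # no physical meaning and breaks the log in the quality index
    ssc <- pmax(val[, "ssc"], 1)
    firmness <- pmax(val[, "firmness"], 0.2)
    L <- pmax(val[, "L"], 1)
    a <- val[, "a"]
    b <- pmax(val[, "b"], 1)
    data.frame(cultivar = cultivar, day = day, ssc = ssc,
               firmness = firmness, L = L, a = a, b = b,
               chroma = sqrt(a^2 + b^2), .theta = theta)
}

#' Simulate a shelf-life quality-parameter table
#'
#' Draws one row per fruit: a ripeness latent (mean increasing with day)
#' drives SSC, firmness, L*, a* and b* linearly with independent Gaussian
#' noise; a second independent latent carries the residual firmness/a*
#' coupling; chroma is derived as the CIELAB chroma `sqrt(a*^2 + b*^2)`.
#' Under the default configuration the day-0 and day-9 cohort means match
#' the configured trajectory endpoints and the induced Pearson structure
#' matches the shelf-life study conditions (SSC rising from ~12 to
#' 16--17 degrees Brix while firmness falls below 8 kg cm^-2, r(SSC,
#' firmness) ~ -0.78, r(b*, chroma) ~ 0.99).
#'
#' Hidden dot-prefixed columns carry the ripeness latent and the per-fruit
#' spectral feature wobble so that [simulateSpectrum()] is a deterministic
#' function of a row.
#'
#' @param config a [SimConfig-class].
#' @param nPerGroup optional override of the per-cell sample size.
#' @param seed integer seed; defaults to the config's.
#' @return a data.frame with columns `cultivar`, `day`, `ssc`, `firmness`,
#'   `L`, `a`, `b`, `chroma` plus hidden generator columns.
#' @examples
#' tab <- simulateQualityTable(simConfig(), seed = 1)
#' aggregate(cbind(ssc, firmness) ~ day, tab, mean)
#' @export
simulateQualityTable <- function(config, nPerGroup = NULL, seed = config@seed) {
    if (!is.null(nPerGroup)) {
        config@nPerGroup <- as.integer(nPerGroup)
        validObject(config)
    }
    withSeed(seed, {
        tab <- drawQuality(config)
        k <- nrow(config@featureCoefficients)
        eta <- sapply(seq_len(k), function(j)
            stats::rnorm(nrow(tab), 0, config@featureNoiseSD[j]))
        eta <- matrix(eta, nrow = nrow(tab))
        colnames(eta) <- paste0(".eta.", rownames(config@featureCoefficients))
        cbind(tab, as.data.frame(eta))
    })
}

# Smooth reflectance baseline: cubic in normalised wavelength, rising from
# the blue into the NIR plateau (coefficients fixed by four anchor points).
baselineCurve <- function(wl) {
    u <- (wl - 400) / 600
    0.28 - 0.115 * u + 1.71 * u^2 - 1.395 * u^3
}

gaussShape <- function(wl, center, width) exp(-(wl - center)^2 / (2 * width^2))

# Feature amplitudes of one quality row, including its stored wobble.
rowFeatures <- function(row, config) {
    f <- drop(signalFeatures(row, config))
    etaCols <- paste0(".eta.", rownames(config@featureCoefficients))
    if (all(etaCols %in% names(row)))
        f <- f + unlist(row[etaCols], use.names = FALSE)
    f
}

# Deterministic (noise-free) spectrum of one quality row.
spectrumSignal <- function(row, axis, config) {
    wl <- axis@wavelengths
    f <- rowFeatures(row, config)
    baselineCurve(wl) -
        f["d420"] * gaussShape(wl, 420, 18) -
        f["d670"] * gaussShape(wl, 670, 28) -
        f["d970"] * gaussShape(wl, 970, 33) +
        f["nir830"] * gaussShape(wl, 830, 70)
}

#' Simulate the mean reflectance spectrum of one fruit
#'
#' The spectrum is a smooth cubic baseline minus Gaussian absorption
#' features -- chlorophyll dips near 420 and 670 nm (tracking a* and b*),
#' the water band near 970 nm (tracking a firmness-linked moisture proxy) --
#' plus a broad near-infrared reflectance shoulder around 830 nm whose level
#' is affine in firmness and SSC, so that day-0 fruit are brighter at 830 nm
#' and show a deeper 670 nm dip than day-9 fruit. Per-band Gaussian noise of
#' SD `config@spectralNoiseSD` is added and the result clamped to [0, 1].
#'
#' With `spectralNoiseSD = 0` the spectrum is a deterministic function of
#' the quality row (including its stored feature wobble), and with all
#' feature coefficients zero it equals the baseline curve exactly.
#'
#' @param row a single-row quality record from [simulateQualityTable()].
#' @param axis a [SpectralAxis-class] (256 bands over 400--1000 nm by
#'   default).
#' @param config the [SimConfig-class] used to generate the row.
#' @param seed optional seed for the band noise.
#' @return numeric reflectance vector in [0, 1], one value per band.
#' @export
simulateSpectrum <- function(row, axis = spectralAxis(), config, seed = NULL) {
    if (nrow(as.data.frame(row)) != 1L)
        stop("simulateSpectrum expects a single quality record")
    s <- spectrumSignal(row, axis, config)
    withSeed(seed, {
        s <- s + stats::rnorm(length(s), 0, config@spectralNoiseSD)
        pmin(pmax(s, 0), 1)
    })
}

#' Simulate a hyperspectral cube for one fruit
#'
#' Renders an elliptical fruit on a dark background: every fruit pixel's
#' spectrum is the fruit's noise-free spectrum plus a smooth, low-amplitude
#' spatial brightness field and per-band Gaussian noise. A flat synthetic
#' white frame and near-zero dark frame are emitted alongside, and the raw
#' cube is constructed by inverting the white/dark correction, so that
#' [radiometricCorrect()] recovers the generating reflectance to machine
#' precision.
#'
#' @param row a single-row quality record.
#' @param axis a [SpectralAxis-class].
#' @param config the generating [SimConfig-class].
#' @param height,width spatial extent in pixels (default 64 x 64, a
#'   desk-scale stand-in for the full 1392 x 1040 detector).
#' @param centerFrac fruit centre as fractions of (height, width).
#' @param axesFrac ellipse semi-axes as fractions of (height, width).
#' @param seed optional seed for the spatial field and band noise.
#' @return a list: `raw` (the raw [HyperCube-class]), `refs`
#'   ([ReferenceFrames-class]), `reflectance` (the generating corrected
#'   cube) and `mask` (logical fruit mask).
#' @export
simulateCube <- function(row, axis = spectralAxis(), config,
                         height = 64L, width = 64L,
                         centerFrac = c(0.5, 0.5), axesFrac = c(0.42, 0.34),
                         seed = NULL) {
    base <- spectrumSignal(row, axis, config)
    nb <- length(base)
    cy <- centerFrac[1] * height; cx <- centerFrac[2] * width
    ry <- axesFrac[1] * height; rx <- axesFrac[2] * width
    rr <- matrix(seq_len(height), height, width)
    cc <- matrix(seq_len(width), height, width, byrow = TRUE)
    mask <- ((rr - cy) / ry)^2 + ((cc - cx) / rx)^2 <= 1
    roiSide <- max(1L, as.integer(round(110 / 1040 * min(height, width))))
    if (sum(mask) < roiSide^2)
        warning(sprintf(
            "fruit mask holds %d pixels, fewer than the %d x %d scaled ROI",
            sum(mask), roiSide, roiSide))
    refl <- withSeed(seed, {
        # smooth brightness field: bilinear interpolation of a coarse grid
        g <- matrix(stats::rnorm(25, 0, config@spatialSD), 5, 5)
        gy <- seq(1, height, length.out = 5); gx <- seq(1, width, length.out = 5)
        fy <- findInterval(seq_len(height), gy, rightmost.closed = TRUE)
        fx <- findInterval(seq_len(width), gx, rightmost.closed = TRUE)
        ty <- (seq_len(height) - gy[fy]) / (gy[pmin(fy + 1, 5)] - gy[fy] + 1e-12)
        tx <- (seq_len(width) - gx[fx]) / (gx[pmin(fx + 1, 5)] - gx[fx] + 1e-12)
        f11 <- g[cbind(rep(fy, width), rep(fx, each = height))]
        f21 <- g[cbind(rep(pmin(fy + 1, 5), width), rep(fx, each = height))]
        f12 <- g[cbind(rep(fy, width), rep(pmin(fx + 1, 5), each = height))]
        f22 <- g[cbind(rep(pmin(fy + 1, 5), width),
                       rep(pmin(fx + 1, 5), each = height))]
        wy <- rep(ty, width); wx <- rep(tx, each = height)
        field <- matrix((1 - wy) * (1 - wx) * f11 + wy * (1 - wx) * f21 +
                        (1 - wy) * wx * f12 + wy * wx * f22, height, width)
        px <- array(0.02, dim = c(height, width, nb))
        for (b in seq_len(nb)) {
            plane <- matrix(0.02, height, width)
            plane[mask] <- base[b] + field[mask]
            px[, , b] <- plane
        }
        px <- px + array(stats::rnorm(length(px), 0, config@spectralNoiseSD),
                         dim = dim(px))
        pmin(pmax(px, 0), 1)
    })
    white <- matrix(4000, height, width)
    dark <- matrix(100, height, width)
    refs <- referenceFrames(white, dark)
    rawData <- refl * (4000 - 100) + 100
    prov <- sprintf("synthetic fruit (day %s)", row$day)
    list(raw = hyperCube(rawData, axis, kind = "raw", provenance = prov),
         refs = refs,
         reflectance = hyperCube(refl, axis, kind = "corrected",
                                 provenance = prov),
         mask = mask)
}
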