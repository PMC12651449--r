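# Default generative parameters for the synthetic shelf-life experiment.
# Loadings and the firmness/a* residual coupling were calibrated once,
# analytically, against the published shelf-life Pearson structure (see the
# methods vignette and inst/scripts/calibrate-generator.R); they are frozen
# here and are not meant to be re-tuned.
defaultTrajectories <- function() {
    m <- rbind(ssc      = c(12, 16.5),
               firmness = c(13.5, 7),
               L        = c(55, 45),
               a        = c(-9, -6),
               b        = c(30, 22))
    colnames(m) <- c("day0", "day9")
    m
}

defaultLoadings <- function() {
    c(ssc = 0.8906, firmness = 0.8758, L = 0.6793, a = 0.5839, b = 0.6340)
}

defaultCoupling <- function() c(firmness = -1.0, a = 0.8677)

# Spectral feature amplitudes (reflectance units) as affine functions of the
# quality parameters: chlorophyll dips at 420/670 nm track a* (and, at
# 670 nm, the yellow pigment b*), the water dip at 970 nm tracks a moisture
# proxy (firmness), and the broad 830 nm NIR level tracks firmness and SSC.
defaultFeatureCoefficients <- function() {
    m <- rbind(
        d420   = c(-0.14,      -0.03,      0,       0,          0),
        d670   = c(-0.315,     -0.10 / 3,  0.0075,  0,          0),
        d970   = c(0.0461538,  0,          0,       0.05 / 6.5, 0),
        nir830 = c(0.0574359,  0,          0,       0.12 / 6.5, -0.04 / 4.5))
    colnames(m) <- c("intercept", "a", "b", "firmness", "ssc")
    m
}

#' Configure the synthetic shelf-life experiment
#'
#' Builds a [SimConfig-class] holding the full generative model: trajectory
#' endpoints, latent-ripeness loadings, the residual firmness/a* coupling,
#' the spectral feature map and the noise levels. The per-fruit feature
#' wobble implied by `explainableFraction` is calibrated here, once,
#' deterministically (see Details).
#'
#' @param nPerGroup fruits per cultivar x day cell (default 30, i.e. 240
#'   fruits under the default two cultivars and four days).
#' @param cultivars cultivar labels.
#' @param days shelf-life days at which cohorts are sampled.
#' @param trajectories 5 x 2 matrix of day-0/day-9 cohort means
#'   (rows ssc, firmness, L, a, b).
#' @param latentLoadings named per-parameter correlations with the ripeness
#'   latent, in (0, 1].
#' @param thetaSD within-day SD of the ripeness latent.
#' @param coupling loadings of firmness and a* on the residual latent.
#' @param featureCoefficients 4 x 5 affine map from (1, a, b, firmness, ssc)
#'   to the spectral feature amplitudes.
#' @param spectralNoiseSD per-band, per-pixel Gaussian noise SD.
#' @param spatialSD SD of the smooth within-fruit brightness field.
#' @param explainableFraction target fraction of quality-index variance
#'   linearly recoverable from noise-free spectra, in (0, 1].
#' @param seed default seed used by the generators.
#'
#' @details `explainableFraction` is realised by adding an independent
#' Gaussian wobble to each fruit's four spectral feature amplitudes.  The
#' wobble SDs are solved at construction time from the second moments of a
#' fixed-seed internal draw so that the best linear predictor of the quality
#' index from the wobbled features attains R-squared equal to the requested
#' fraction (or the noise-free ceiling, if that is lower). The calibration
#' is deterministic and independent of the seeds later used for data
#' generation.
#'
#' @return a validated [SimConfig-class].
#' @examples
#' cfg <- simConfig()
#' cfg
#' @export
simConfig <- function(nPerGroup = 30L,
                      cultivars = c("A", "B"),
                      days = c(0, 3, 6, 9),
                      trajectories = defaultTrajectories(),
                      latentLoadings = defaultLoadings(),
                      thetaSD = 0.12,
                      coupling = defaultCoupling(),
                      featureCoefficients = defaultFeatureCoefficients(),
                      spectralNoiseSD = 0.005,
                      spatialSD = 0.01,
                      explainableFraction = 0.9,
                      seed = 1L) {
    cfg <- new("SimConfig",
        nPerGroup = as.integer(nPerGroup), cultivars = cultivars,
        days = as.numeric(days), trajectories = trajectories,
        latentLoadings = latentLoadings, thetaSD = thetaSD,
        coupling = coupling, featureCoefficients = featureCoefficients,
        featureNoiseSD = rep(0, nrow(featureCoefficients)),
        spectralNoiseSD = spectralNoiseSD, spatialSD = spatialSD,
        explainableFraction = explainableFraction, seed = as.integer(seed))
    qualityNoiseSDs(cfg)  # errors early on non-PSD configurations
    cfg@featureNoiseSD <- calibrateFeatureNoise(cfg)
    cfg
}

setMethod("show", "SimConfig", function(object) {
    cat(sprintf(
        "SimConfig: %d cultivars x %d days x %d fruits = %d fruits\n",
        length(object@cultivars), length(object@days), object@nPerGroup,
        length(object@cultivars) * length(object@days) * object@nPerGroup))
    cat(sprintf("  explainable fraction %.2f, band noise SD %.3f, seed %d\n",
                object@explainableFraction, object@spectralNoiseSD,
                object@seed))
})

# Population SD of the ripeness latent: between-day spread of the cohort
# means (days mapped to [0, 1]) plus the within-day SD.
thetaTotalSD <- function(config) {
    mu <- config@days / max(config@days, 1)
    sqrt(mean((mu - mean(mu))^2) + config@thetaSD^2)
}

# Marginal noise SDs implied by the latent loadings; errors if a loading
# (with the residual coupling) implies negative noise variance, i.e. the
# configured correlation structure is not positive semi-definite.
qualityNoiseSDs <- function(config) {
    sdT <- thetaTotalSD(config)
    slopes <- config@trajectories[, 2] - config@trajectories[, 1]
    sigma <- abs(slopes) * sdT / config@latentLoadings
    cc <- c(ssc = 0, firmness = unname(config@coupling["firmness"]),
            L = 0, a = unname(config@coupling["a"]), b = 0)
    nv <- sigma^2 - (slopes * sdT)^2 - cc^2
    if (any(nv < -1e-10))
        stop("configuration implies negative residual variance for ",
             paste(names(nv)[nv < -1e-10], collapse = ", "),
             ": the implied correlation matrix is not positive semi-definite")
    sqrt(pmax(nv, 0))
}

# Full covariance matrix of (ssc, firmness, L, a, b) implied by the config.
qualityCovariance <- function(config) {
    sdT <- thetaTotalSD(config)
    slopes <- config@trajectories[, 2] - config@trajectories[, 1]
    cc <- c(ssc = 0, firmness = unname(config@coupling["firmness"]),
            L = 0, a = unname(config@coupling["a"]), b = 0)
    s <- qualityNoiseSDs(config)
    outer(slopes, slopes) * sdT^2 + outer(cc, cc) + diag(s^2)
}

# Noise-free ("signal") spectral feature amplitudes for quality rows.
signalFeatures <- function(table, config) {
    M <- cbind(1, table$a, table$b, table$firmness, table$ssc)
    F <- M %*% t(config@featureCoefficients)
    colnames(F) <- rownames(config@featureCoefficients)
    F
}

# Solve the per-feature wobble SDs delivering the requested explainable
# fraction. Uses a fixed-seed internal draw for the second moments, then the
# closed-form R-squared of the best linear predictor under added diagonal
# noise; deterministic by construction.
calibrateFeatureNoise <- function(config, nDraw = 20000L) {
    f <- config@explainableFraction
    k <- nrow(config@featureCoefficients)
    if (f >= 1) return(rep(0, k))
    tab <- withSeed(77003L, drawQuality(config, nTotal = nDraw))
    S <- signalFeatures(tab, config)
    y <- computeKCQI(tab)
    vS <- stats::var(S)
    if (all(abs(vS) < 1e-14)) return(rep(0, k))
    cSy <- stats::cov(S, y)
    vy <- stats::var(y)
    baseSD <- sqrt(pmax(diag(vS), 0))
    r2At <- function(w) {
        D <- diag(w^2 * baseSD^2, k)
        drop(t(cSy) %*% solve(vS + D, cSy)) / vy
    }
    if (r2At(0) <= f) return(rep(0, k))  # ceiling already at/below target
    w <- stats::uniroot(function(w) r2At(w) - f, c(0, 50), tol = 1e-8)$root
    w * baseSD
}
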