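#' @import methods
NULL

#' Spectral axis of a hyperspectral instrument
#'
#' Maps band indices to wavelengths in nanometres. The default axis models a
#' 256-band visible/near-infrared instrument spanning 400--1000 nm on an
#' evenly spaced grid (sampling interval ~2.35 nm).
#'
#' @slot wavelengths numeric vector of strictly increasing wavelengths (nm).
#' @export
setClass("SpectralAxis", representation(wavelengths = "numeric"))

setValidity("SpectralAxis", function(object) {
    w <- object@wavelengths
    if (length(w) < 2L) return("a spectral axis needs at least two bands")
    if (anyNA(w)) return("wavelengths must not contain NA")
    if (any(diff(w) <= 0)) return("wavelengths must be strictly increasing")
    TRUE
})

#' Hyperspectral data cube
#'
#' A height x width x bands array of raw intensities or relative reflectance,
#' together with its spectral axis. `kind` records whether the values are raw
#' camera counts or white/dark-corrected reflectance; corrected values may
#' exceed 1 on specular pixels and are deliberately not clipped.
#'
#' @slot data 3-d numeric array, rows x columns x bands.
#' @slot axis [SpectralAxis-class] whose length matches `dim(data)[3]`.
#' @slot kind `"raw"` or `"corrected"`.
#' @slot provenance free-text origin (file path or simulation seed).
#' @export
setClass("HyperCube", representation(
    data = "array", axis = "SpectralAxis",
    kind = "character", provenance = "character"))

setValidity("HyperCube", function(object) {
    d <- dim(object@data)
    if (length(d) != 3L) return("cube data must be a 3-d array")
    if (d[3] != length(object@axis@wavelengths))
        return(sprintf("cube has %d bands but axis has %d wavelengths",
                       d[3], length(object@axis@wavelengths)))
    if (!object@kind %in% c("raw", "corrected"))
        return("kind must be 'raw' or 'corrected'")
    TRUE
})

#' White and dark reference frames for radiometric correction
#'
#' Holds the white-panel and dark-current reference images used to convert
#' raw intensities to relative reflectance. Each reference is either a single
#' frame (rows x columns, applied to every band) or a full cube
#' (rows x columns x bands).
#'
#' @slot white numeric matrix or 3-d array of white-panel intensities.
#' @slot dark numeric matrix or 3-d array of dark-current intensities.
#' @export
setClass("ReferenceFrames", representation(white = "array", dark = "array"))

setValidity("ReferenceFrames", function(object) {
    dw <- dim(object@white); dd <- dim(object@dark)
    if (!length(dw) %in% 2:3 || !length(dd) %in% 2:3)
        return("references must be matrices or 3-d arrays")
    if (!identical(dw[1:2], dd[1:2]))
        return("white and dark references must share spatial dimensions")
    TRUE
})

#' Rectangular region of interest
#'
#' Pixel window over which the representative mean spectrum of a fruit is
#' taken. Offsets are 0-based and extents half-open, so the covered rows are
#' `rowOffset + 1 ... rowOffset + height` in R's 1-based indexing.
#'
#' @slot rowOffset,colOffset 0-based offsets of the top-left corner.
#' @slot height,width extent in pixels.
#' @export
setClass("ROI", representation(
    rowOffset = "integer", colOffset = "integer",
    height = "integer", width = "integer"))

setValidity("ROI", function(object) {
    if (object@height < 1L || object@width < 1L)
        return("ROI extents must be positive")
    if (object@rowOffset < 0L || object@colOffset < 0L)
        return("ROI offsets must be non-negative")
    TRUE
})

#' Synthetic shelf-life experiment configuration
#'
#' Parameters of the generative model behind [simulateQualityTable()],
#' [simulateSpectrum()] and [simulateCube()]: a scalar ripeness latent per
#' fruit whose mean increases with shelf-life day drives all six quality
#' parameters, with per-parameter loadings calibrated so the induced Pearson
#' structure matches the shelf-life study conditions; a second, independent
#' latent shared only by firmness and a* carries their residual coupling.
#' Spectra are a smooth baseline minus Gaussian absorption features whose
#' depths are affine in the quality parameters.
#'
#' @slot nPerGroup fruits per cultivar x day cell (default 30).
#' @slot cultivars cultivar labels (default two).
#' @slot days sampled shelf-life days (default 0, 3, 6, 9).
#' @slot trajectories 5 x 2 matrix of day-0 and day-9 cohort means for
#'   ssc, firmness, L, a, b (chroma is derived as sqrt(a^2 + b^2)).
#' @slot latentLoadings named correlations of each simulated parameter with
#'   the ripeness latent; marginal noise SDs are derived from these.
#' @slot thetaSD within-day SD of the ripeness latent.
#' @slot coupling loadings of firmness and a* on the residual coupling latent.
#' @slot featureCoefficients 4 x 5 matrix mapping (1, a, b, firmness, ssc) to
#'   the four spectral feature amplitudes (420/670/970 nm dips, 830 nm level).
#' @slot featureNoiseSD per-feature SD of the fruit-level feature wobble,
#'   calibrated from `explainableFraction` at construction time.
#' @slot spectralNoiseSD per-band Gaussian noise SD (reflectance units).
#' @slot spatialSD SD of the smooth within-fruit spatial brightness field.
#' @slot explainableFraction fraction of KCQI variance linearly encoded in
#'   noise-free spectra, in (0, 1].
#' @slot seed default integer seed for the generators.
#' @export
setClass("SimConfig", representation(
    nPerGroup = "integer", cultivars = "character", days = "numeric",
    trajectories = "matrix", latentLoadings = "numeric", thetaSD = "numeric",
    coupling = "numeric", featureCoefficients = "matrix",
    featureNoiseSD = "numeric", spectralNoiseSD = "numeric",
    spatialSD = "numeric", explainableFraction = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
    if (object@nPerGroup < 2L) return("nPerGroup must be at least 2")
    if (object@explainableFraction <= 0 || object@explainableFraction > 1)
        return("explainableFraction must lie in (0, 1]")
    if (!identical(rownames(object@trajectories),
                   c("ssc", "firmness", "L", "a", "b")))
        return("trajectories must have rows ssc, firmness, L, a, b")
    ll <- object@latentLoadings
    if (!identical(names(ll), c("ssc", "firmness", "L", "a", "b")))
        return("latentLoadings must be named ssc, firmness, L, a, b")
    if (any(ll <= 0) || any(ll > 1))
        return("latent loadings must lie in (0, 1]; the implied noise variance is negative otherwise (non-positive-semi-definite configuration)")
    if (object@thetaSD < 0 || object@spectralNoiseSD < 0 ||
        object@spatialSD < 0 || any(object@featureNoiseSD < 0))
        return("noise SDs must be non-negative")
    TRUE
})

#' Factor-analysis model of the quality parameters
#'
#' Output of [factorAnalysis()]: adequacy diagnostics, eigenstructure of the
#' correlation matrix, and the varimax-rotated loading matrix used to select
#' the parameters entering the composite quality index.
#'
#' @slot correlation p x p Pearson correlation matrix.
#' @slot kmo Kaiser-Meyer-Olkin sampling adequacy in [0, 1] (NA if not computed).
#' @slot bartlett named vector (chi2, df, p) of Bartlett's sphericity test.
#' @slot eigenvalues all p eigenvalues, decreasing.
#' @slot cumulativeVariance cumulative explained variance, percent.
#' @slot loadings p x k rotated loading matrix over the retained factors.
#' @slot retainedK number of retained factors.
#' @slot rotation rotation applied ("varimax" or "none").
#' @export
setClass("FactorModel", representation(
    correlation = "matrix", kmo = "numeric", bartlett = "numeric",
    eigenvalues = "numeric", cumulativeVariance = "numeric",
    loadings = "matrix", retainedK = "integer", rotation = "character"))

#' Spectra paired with the response they predict
#'
#' An n x p matrix of per-fruit mean reflectance spectra, the response vector
#' (the composite quality index) and, once [spxySplit()] has been applied,
#' the calibration/prediction membership of every sample.
#'
#' @slot X n x p reflectance matrix (no missing values).
#' @slot y numeric response of length n.
#' @slot axis [SpectralAxis-class] with p bands.
#' @slot split per-sample labels, `"calibration"`/`"prediction"`, or `NA`
#'   before splitting.
#' @export
setClass("SpectralDataset", representation(
    X = "matrix", y = "numeric", axis = "SpectralAxis", split = "character"))

setValidity("SpectralDataset", function(object) {
    if (nrow(object@X) != length(object@y))
        return("X and y disagree on the number of samples")
    if (ncol(object@X) != length(object@axis@wavelengths))
        return("X and the spectral axis disagree on the number of bands")
    if (anyNA(object@X) || anyNA(object@y))
        return("X and y must not contain missing values")
    if (length(object@split) != nrow(object@X))
        return("split labels must cover every sample")
    ok <- object@split %in% c("calibration", "prediction") | is.na(object@split)
    if (!all(ok)) return("split labels must be 'calibration' or 'prediction'")
    TRUE
})

#' Characteristic-band subset
#'
#' Bands retained by one of the selection algorithms, with the wavelengths
#' they map to and the algorithm's diagnostic trace (RMSE path, retained-count
#' path or per-band selection probabilities).
#'
#' @slot method `"spa"`, `"cars"`, `"rfrog"` or `"full"`.
#' @slot indices sorted, unique 1-based band positions.
#' @slot wavelengths the corresponding wavelengths (nm).
#' @slot diagnostics method-specific trace, as a list.
#' @export
setClass("BandSubset", representation(
    method = "character", indices = "integer",
    wavelengths = "numeric", diagnostics = "list"))

setValidity("BandSubset", function(object) {
    i <- object@indices
    if (is.unsorted(i, strictly = TRUE)) return("indices must be sorted and unique")
    if (length(i) && (min(i) < 1L)) return("indices must be positive")
    if (length(i) != length(object@wavelengths))
        return("indices and wavelengths disagree in length")
    TRUE
})

#' A trained quality-index regression model
#'
#' Wraps a fitted PLSR, random-forest or 1-d convolutional network backend
#' together with the band subset and standardisation statistics it was
#' trained with, its per-epoch training history (networks only) and its
#' calibration/prediction evaluation metrics.
#'
#' @slot kind `"plsr"`, `"rf"` or `"cnn"`.
#' @slot fit backend-specific fitted object.
#' @slot bands 1-based band indices the model consumes.
#' @slot xCenter,xScale per-band standardisation statistics from the
#'   calibration set (length 0 when the backend standardises internally).
#' @slot yCenter,yScale response standardisation (0/1 when unused).
#' @slot history per-epoch training trace (`epoch`, `loss`, `rmse`) for the
#'   network backend; empty otherwise.
#' @slot calibration,prediction evaluation metric lists
#'   (`r2`, `rmse` and, for the prediction set, `rpd`).
#' @export
setClass("FitResult", representation(
    kind = "character", fit = "ANY", bands = "integer",
    xCenter = "numeric", xScale = "numeric",
    yCenter = "numeric", yScale = "numeric",
    history = "data.frame", calibration = "list", prediction = "list"))

#' Pixel-wise quality-index map
#'
#' Per-pixel quality-index predictions over the fruit mask of a corrected
#' cube, with the colour scale used for rendering.
#'
#' @slot values height x width matrix; `NA` off the fruit mask.
#' @slot mask logical fruit mask of the same shape.
#' @slot scaleRange length-2 numeric (vmin, vmax), vmin < vmax.
#' @slot colormap palette name passed to [grDevices::hcl.colors()].
#' @export
setClass("KCQIMap", representation(
    values = "matrix", mask = "matrix",
    scaleRange = "numeric", colormap = "character"))

setValidity("KCQIMap", function(object) {
    if (!identical(dim(object@values), dim(object@mask)))
        return("values and mask must share dimensions")
    if (any(!is.finite(object@values[object@mask])))
        return("values must be finite on the fruit mask")
    if (length(object@scaleRange) != 2L ||
        !(object@scaleRange[1] < object@scaleRange[2]))
        return("scaleRange must be (vmin, vmax) with vmin < vmax")
    TRUE
})
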