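#' Construct a spectral axis
#'
#' @param nBands number of bands (default 256).
#' @param range wavelength span in nm, inclusive (default 400--1000).
#' @param wavelengths explicit wavelength grid; overrides `nBands`/`range`.
#'
#' @details The default reproduces a 256-band instrument covering
#' 400--1000 nm on an even grid, giving a sampling interval of about
#' 2.35 nm. (Instrument spec sheets often quote a coarser optical
#' resolution -- the FWHM of the slit function -- which is a different
#' quantity from the sampling interval and is not modelled here.)
#'
#' @return a [SpectralAxis-class].
#' @examples
#' ax <- spectralAxis()
#' nBands(ax)
#' bandNearest(ax, 830)
#' @export
spectralAxis <- function(nBands = 256L, range = c(400, 1000),
                         wavelengths = NULL) {
    if (is.null(wavelengths))
        wavelengths <- seq(range[1], range[2], length.out = nBands)
    new("SpectralAxis", wavelengths = as.numeric(wavelengths))
}

#' @rdname SpectralAxis-class
#' @export
setMethod("nBands", "SpectralAxis", function(x) length(x@wavelengths))

#' @rdname SpectralAxis-class
#' @export
setMethod("wavelengths", "SpectralAxis", function(x) x@wavelengths)

#' @rdname SpectralAxis-class
#' @export
setMethod("nBands", "HyperCube", function(x) nBands(x@axis))

#' @rdname SpectralAxis-class
#' @export
setMethod("wavelengths", "HyperCube", function(x) wavelengths(x@axis))

#' Band index nearest to a wavelength
#'
#' @param axis a [SpectralAxis-class].
#' @param nm wavelength(s) in nanometres.
#' @return integer band indices (1-based).
#' @export
bandNearest <- function(axis, nm) {
    vapply(nm, function(w) which.min(abs(axis@wavelengths - w)), integer(1))
}

setMethod("show", "SpectralAxis", function(object) {
    w <- object@wavelengths
    cat(sprintf("SpectralAxis: %d bands, %.1f-%.1f nm (step ~%.2f nm)\n",
                length(w), min(w), max(w), mean(diff(w))))
})
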