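#' @rdname SpectralAxis-class
#' @param object,x a `SpectralAxis` (or an object carrying one).
#' @export
setGeneric("nBands", function(x) standardGeneric("nBands"))

#' @rdname SpectralAxis-class
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname radiometricCorrect
#' @export
setGeneric("radiometricCorrect",
    function(raw, refs) standardGeneric("radiometricCorrect"))

#' @rdname autoROI
#' @export
setGeneric("autoROI", function(cube, size, ...) standardGeneric("autoROI"))

#' @rdname meanSpectrum
#' @export
setGeneric("meanSpectrum", function(cube, roi) standardGeneric("meanSpectrum"))

#' @rdname fruitMask
#' @export
setGeneric("fruitMask", function(cube, ...) standardGeneric("fruitMask"))

#' @rdname predictMap
#' @export
setGeneric("predictMap",
    function(cube, model, ...) standardGeneric("predictMap"))
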