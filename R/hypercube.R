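#' Construct a hyperspectral cube
#'
#' @param data rows x columns x bands numeric array.
#' @param axis a [SpectralAxis-class]; defaults to an index axis.
#' @param kind `"raw"` or `"corrected"`.
#' @param provenance free-text origin annotation.
#' @return a [HyperCube-class].
#' @export
hyperCube <- function(data, axis = NULL, kind = "raw", provenance = "") {
    if (is.null(axis)) axis <- spectralAxis(wavelengths = seq_len(dim(data)[3]))
    new("HyperCube", data = data, axis = axis, kind = kind,
        provenance = provenance)
}

#' @rdname hyperCube
#' @param x a `HyperCube`.
#' @export
cubeData <- function(x) x@data

#' @rdname hyperCube
#' @export
cubeKind <- function(x) x@kind

setMethod("show", "HyperCube", function(object) {
    d <- dim(object@data)
    cat(sprintf("HyperCube (%s): %d x %d pixels, %d bands (%.0f-%.0f nm)\n",
                object@kind, d[1], d[2], d[3],
                min(object@axis@wavelengths), max(object@axis@wavelengths)))
    if (nzchar(object@provenance))
        cat("  provenance:", object@provenance, "\n")
})

#' Bundle white and dark reference frames
#'
#' @param white,dark numeric matrices (rows x columns) or arrays
#'   (rows x columns x bands) of reference intensities.
#' @return a [ReferenceFrames-class].
#' @export
referenceFrames <- function(white, dark) {
    new("ReferenceFrames", white = as.array(white), dark = as.array(dark))
}

#' Construct a region of interest
#'
#' @param rowOffset,colOffset 0-based offsets of the top-left corner.
#' @param height,width extents in pixels.
#' @return an [ROI-class].
#' @export
roi <- function(rowOffset, colOffset, height, width) {
    new("ROI", rowOffset = as.integer(rowOffset),
        colOffset = as.integer(colOffset),
        height = as.integer(height), width = as.integer(width))
}

setMethod("show", "ROI", function(object) {
    cat(sprintf("ROI: %d x %d pixels at (row %d, col %d) [0-based, half-open]\n",
                object@height, object@width, object@rowOffset,
                object@colOffset))
})

# Expand a reference (frame or cube) to cube dimensions for element-wise use.
expandReference <- function(ref, d) {
    dr <- dim(ref)
    if (length(dr) == 2L) {
        if (!identical(as.integer(dr), as.integer(d[1:2])))
            stop("reference frame does not match the cube's spatial dimensions")
        array(rep(as.numeric(ref), d[3]), dim = d)
    } else {
        if (!identical(as.integer(dr), as.integer(d)))
            stop("reference cube does not match the cube's dimensions")
        ref
    }
}

#' White/dark radiometric correction
#'
#' Converts raw intensities to relative reflectance, element-wise:
#' \deqn{R_c = (I_r - I_d) / (I_w - I_d)}
#' where \eqn{I_r} is the raw cube and \eqn{I_w}, \eqn{I_d} the white and
#' dark references. Correction is invariant to a joint rescaling of all
#' three intensities. Values above 1 (specular pixels) are retained.
#'
#' @param raw a raw [HyperCube-class].
#' @param refs a [ReferenceFrames-class] compatible with the cube.
#' @return a corrected [HyperCube-class].
#' @export
setMethod("radiometricCorrect", signature("HyperCube", "ReferenceFrames"),
    function(raw, refs) {
        d <- dim(raw@data)
        w <- expandReference(refs@white, d)
        k <- expandReference(refs@dark, d)
        denom <- w - k
        if (any(denom <= 0)) {
            bad <- which(apply(denom <= 0, 3, any))
            stop("white reference does not exceed dark reference at band(s) ",
                 paste(bad, collapse = ", "),
                 "; cannot divide in the correction")
        }
        new("HyperCube", data = (raw@data - k) / denom, axis = raw@axis,
            kind = "corrected", provenance = raw@provenance)
    })

#' Fruit mask of a cube
#'
#' Segments fruit from background by Otsu-thresholding the image at the band
#' nearest `nm` (default 830 nm, where fruit tissue is bright and the stage
#' dark). Deterministic.
#'
#' @param cube a [HyperCube-class].
#' @param nm wavelength (nm) of the thresholding band.
#' @return logical rows x columns matrix, `TRUE` on fruit pixels.
#' @export
setMethod("fruitMask", "HyperCube", function(cube, nm = 830) {
    img <- cube@data[, , bandNearest(cube@axis, nm)]
    rng <- range(img)
    if (diff(rng) == 0) stop("cannot segment a spatially constant band image")
    thr <- EBImage::otsu(img, range = rng)
    img > thr
})

#' Default ROI side length for a cube
#'
#' Scales the full-instrument 110-pixel ROI (on a 1392 x 1040 detector)
#' proportionally to the cube's smaller spatial dimension.
#'
#' @param cube a [HyperCube-class].
#' @return integer side length in pixels.
#' @export
defaultROISize <- function(cube) {
    max(1L, as.integer(round(110 / 1040 * min(dim(cube@data)[1:2]))))
}

#' Automatic region-of-interest placement
#'
#' Places a square ROI of the requested size centred on the centroid of the
#' fruit mask (see [fruitMask()]), clipped to stay inside the cube. This is a
#' reproducible stand-in for the manual delineation of the principal scanned
#' area of the fruit.
#'
#' @param cube a [HyperCube-class].
#' @param size ROI side length in pixels; defaults to [defaultROISize()].
#' @param nm thresholding wavelength forwarded to [fruitMask()].
#' @return an [ROI-class].
#' @export
setMethod("autoROI", "HyperCube", function(cube, size, nm = 830) {
    d <- dim(cube@data)
    if (missing(size)) size <- defaultROISize(cube)
    size <- as.integer(size)
    if (size > d[1] || size > d[2])
        stop("requested ROI size exceeds the cube's spatial extent")
    mask <- fruitMask(cube, nm = nm)
    if (sum(mask) < size^2)
        stop(sprintf(
            "fruit mask holds %d pixels, fewer than the %d x %d ROI requires",
            sum(mask), size, size))
    ctr <- which(mask, arr.ind = TRUE)
    cr <- mean(ctr[, 1]); cc <- mean(ctr[, 2])
    r0 <- as.integer(round(cr - size / 2)); c0 <- as.integer(round(cc - size / 2))
    r0 <- min(max(r0, 0L), d[1] - size)
    c0 <- min(max(c0, 0L), d[2] - size)
    roi(r0, c0, size, size)
})

#' Mean spectrum over a region of interest
#'
#' Per-band arithmetic mean of all pixels inside the ROI.
#'
#' @param cube a [HyperCube-class].
#' @param roi an [ROI-class]; defaults to the whole cube.
#' @return numeric reflectance (or intensity) vector of length `nBands(cube)`.
#' @export
setMethod("meanSpectrum", signature("HyperCube", "ROI"), function(cube, roi) {
    d <- dim(cube@data)
    rows <- roi@rowOffset + seq_len(roi@height)
    cols <- roi@colOffset + seq_len(roi@width)
    if (max(rows) > d[1] || max(cols) > d[2])
        stop("ROI extends beyond the cube bounds")
    sub <- cube@data[rows, cols, , drop = FALSE]
    apply(sub, 3, mean)
})

#' @rdname meanSpectrum
#' @export
setMethod("meanSpectrum", signature("HyperCube", "missing"),
    function(cube, roi) apply(cube@data, 3, mean))
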