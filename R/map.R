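#' Pixel-wise quality-index prediction over a cube
#'
#' Applies a trained model to every fruit-mask pixel of a corrected cube:
#' each pixel's spectrum is restricted to the model's band subset,
#' standardised with the model's calibration statistics and passed through
#' the model. Background pixels are masked out.
#'
#' @param cube a *corrected* [HyperCube-class].
#' @param model a [FitResult-class].
#' @param mask logical fruit mask; defaults to [fruitMask()] on the cube.
#' @param scaleRange colour-scale limits `(vmin, vmax)`; defaults to the
#'   range of the predicted values. Fix these across a day series so maps
#'   stay visually comparable.
#' @param colormap palette name for [grDevices::hcl.colors()].
#' @return a [KCQIMap-class].
#' @export
setMethod("predictMap", signature("HyperCube", "FitResult"),
    function(cube, model, mask = NULL, scaleRange = NULL,
             colormap = "viridis") {
        if (cube@kind != "corrected")
            stop("predictMap needs a corrected cube; run radiometricCorrect()")
        d <- dim(cube@data)
        if (max(model@bands) > d[3])
            stop("model band indices exceed the cube's ", d[3], " bands")
        if (is.null(mask)) mask <- fruitMask(cube)
        flat <- matrix(cube@data, d[1] * d[2], d[3])
        specs <- flat[as.vector(mask), model@bands, drop = FALSE]
        vals <- matrix(NA_real_, d[1], d[2])
        vals[mask] <- predict(model, specs)
        if (is.null(scaleRange)) {
            scaleRange <- range(vals[mask])
            if (diff(scaleRange) == 0) scaleRange <- scaleRange + c(-0.5, 0.5)
        }
        new("KCQIMap", values = vals, mask = mask,
            scaleRange = as.numeric(scaleRange), colormap = colormap)
    })

setMethod("show", "KCQIMap", function(object) {
    cat(sprintf("KCQIMap: %d x %d pixels, %d on fruit mask\n",
                nrow(object@values), ncol(object@values), sum(object@mask)))
    if (any(object@mask))
        cat(sprintf("  value range %.3f-%.3f (scale %.3f-%.3f)\n",
                    min(object@values[object@mask]),
                    max(object@values[object@mask]),
                    object@scaleRange[1], object@scaleRange[2]))
})

#' @rdname predictMap
#' @param map a [KCQIMap-class].
#' @return `mapMean`: mean predicted value over the fruit mask.
#' @export
mapMean <- function(map) mean(map@values[map@mask])

# Map values onto palette indices under the map's fixed scale; clipping to
# the scale range happens here (display only), never on the values.
mapColorIndex <- function(map, nColors = 256L) {
    v <- pmin(pmax(map@values, map@scaleRange[1]), map@scaleRange[2])
    idx <- floor((v - map@scaleRange[1]) /
                 diff(map@scaleRange) * (nColors - 1L)) + 1L
    idx[!map@mask] <- NA_integer_
    idx
}

#' Render a quality-index map to PNG
#'
#' Writes a pseudocolour image with an adjacent colourbar. Two maps sharing
#' the same `scaleRange` map identical values to identical colours, so a
#' day series rendered with a common scale is visually comparable.
#'
#' @param map a [KCQIMap-class].
#' @param path output PNG path.
#' @param width,height device size in pixels.
#' @return `path`, invisibly. An all-masked map yields a background-only
#'   image with a warning.
#' @export
renderMap <- function(map, path, width = 480L, height = 420L) {
    if (!any(map@mask))
        warning("map has no fruit pixels; rendering background only")
    nColors <- 256L
    pal <- grDevices::hcl.colors(nColors, map@colormap)
    idx <- mapColorIndex(map, nColors)
    grDevices::png(path, width = width, height = height)
    on.exit(grDevices::dev.off())
    graphics::layout(matrix(1:2, 1, 2), widths = c(4, 1))
    graphics::par(mar = c(1, 1, 2, 1))
    graphics::plot.new()
    graphics::plot.window(c(0, 1), c(0, 1), xaxs = "i", yaxs = "i")
    graphics::title("quality index")
    graphics::rasterImage(
        grDevices::as.raster(matrix(ifelse(is.na(idx), "#202020", pal[idx]),
                                    nrow(idx), ncol(idx))),
        0, 0, 1, 1, interpolate = FALSE)
    graphics::par(mar = c(1, 1, 2, 3))
    graphics::image(z = matrix(seq_len(nColors), nrow = 1), col = pal,
                    axes = FALSE)
    graphics::axis(4, at = c(0, 0.5, 1),
                   labels = sprintf("%.2f", seq(map@scaleRange[1],
                                                map@scaleRange[2],
                                                length.out = 3)),
                   las = 1)
    invisible(path)
}
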