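# ENVI raster I/O: plain-text header (.hdr) + flat binary payload. Only the
# keys this package writes are interpreted; unknown keys are ignored.

enviDataTypes <- c("4" = "float32", "5" = "float64")

#' Write a cube in ENVI format
#'
#' Writes `<basePath>.raw` (flat binary, little-endian) and `<basePath>.hdr`
#' (ASCII header with samples/lines/bands/interleave/data type and the
#' wavelength list in nanometres). `float64` gives a bit-exact round trip
#' through [readENVI()].
#'
#' @param cube a [HyperCube-class].
#' @param basePath output path without extension.
#' @param interleave `"bsq"`, `"bil"` or `"bip"`.
#' @param dataType 5 (float64, default) or 4 (float32).
#' @return `basePath`, invisibly.
#' @export
writeENVI <- function(cube, basePath, interleave = c("bsq", "bil", "bip"),
                      dataType = 5L) {
    interleave <- match.arg(interleave)
    if (!as.character(dataType) %in% names(enviDataTypes))
        stop("unsupported ENVI data type ", dataType,
             " (supported: 4 = float32, 5 = float64)")
    d <- dim(cube@data)                       # lines, samples, bands
    lines <- d[1]; samples <- d[2]; bands <- d[3]
    # in-memory order is [line, sample, band]; permute so the file runs
    # sample-fastest within the interleave's nesting
    perm <- switch(interleave,
        bsq = c(2, 1, 3),   # sample, line, band
        bil = c(2, 3, 1),   # sample, band, line
        bip = c(3, 2, 1))   # band, sample, line
    vec <- as.vector(aperm(cube@data, perm))
    con <- file(paste0(basePath, ".raw"), "wb")
    on.exit(close(con))
    writeBin(as.numeric(vec), con,
             size = if (dataType == 4L) 4L else 8L, endian = "little")
    hdr <- c(
        "ENVI",
        "description = { written by the kcqi package }",
        sprintf("samples = %d", samples),
        sprintf("lines = %d", lines),
        sprintf("bands = %d", bands),
        "header offset = 0",
        "file type = ENVI Standard",
        sprintf("data type = %d", dataType),
        sprintf("interleave = %s", interleave),
        "byte order = 0",
        "wavelength units = Nanometers",
        sprintf("wavelength = { %s }",
                paste(format(cube@axis@wavelengths, trim = TRUE, digits = 15),
                      collapse = ", ")))
    writeLines(hdr, paste0(basePath, ".hdr"))
    invisible(basePath)
}

# Parse an ENVI header into a named list of raw string values.
parseENVIHeader <- function(hdrPath) {
    txt <- readLines(hdrPath, warn = FALSE)
    if (!length(txt) || !grepl("^ENVI", txt[1]))
        stop("malformed ENVI header: missing leading 'ENVI' magic in ", hdrPath)
    out <- list()
    lines <- txt[-1]
    i <- 1L
    while (i <= length(lines)) {
        ln <- lines[i]
        if (grepl("=", ln, fixed = TRUE)) {
            key <- tolower(trimws(sub("=.*$", "", ln)))
            val <- trimws(sub("^[^=]*=", "", ln))
            if (grepl("\\{", val) && !grepl("\\}", val)) {
                while (i < length(lines) && !grepl("\\}", lines[i])) {
                    i <- i + 1L
                    val <- paste(val, trimws(lines[i]))
                }
            }
            out[[key]] <- val
        }
        i <- i + 1L
    }
    out
}

#' Read a cube written in ENVI format
#'
#' @param basePath path to the data file with or without its `.raw`/`.hdr`
#'   extension; the header is looked up next to the payload.
#' @return a [HyperCube-class] of kind `"raw"` (correction state is not part
#'   of the format; re-tag via [hyperCube()] if the file holds reflectance).
#'   A header without a wavelength list yields an index-valued axis with a
#'   warning. Malformed headers, unsupported interleaves/data types and
#'   truncated payloads are reported distinctly.
#' @export
readENVI <- function(basePath) {
    base <- sub("\\.(raw|hdr|img)$", "", basePath)
    hdrPath <- paste0(base, ".hdr")
    rawPath <- paste0(base, ".raw")
    if (!file.exists(hdrPath)) stop("ENVI header not found: ", hdrPath)
    if (!file.exists(rawPath)) stop("ENVI payload not found: ", rawPath)
    h <- parseENVIHeader(hdrPath)
    need <- c("samples", "lines", "bands", "data type", "interleave")
    miss <- setdiff(need, names(h))
    if (length(miss))
        stop("malformed ENVI header: missing key(s) ",
             paste(miss, collapse = ", "))
    samples <- as.integer(h[["samples"]]); lines <- as.integer(h[["lines"]])
    bands <- as.integer(h[["bands"]])
    dt <- trimws(h[["data type"]])
    if (!dt %in% names(enviDataTypes))
        stop("unsupported ENVI data type ", dt,
             " (supported: 4 = float32, 5 = float64)")
    interleave <- tolower(trimws(h[["interleave"]]))
    if (!interleave %in% c("bsq", "bil", "bip"))
        stop("interleave mismatch: unknown interleave '", interleave, "'")
    size <- if (dt == "4") 4L else 8L
    n <- as.numeric(samples) * lines * bands
    actual <- file.info(rawPath)$size
    if (actual < n * size)
        stop(sprintf(
            "truncated ENVI payload: expected %d bytes, found %d", n * size,
            actual))
    con <- file(rawPath, "rb")
    on.exit(close(con))
    vec <- readBin(con, what = "numeric", n = n, size = size,
                   endian = "little")
    a <- switch(interleave,
        bsq = aperm(array(vec, c(samples, lines, bands)), c(2, 1, 3)),
        bil = aperm(array(vec, c(samples, bands, lines)), c(3, 1, 2)),
        bip = aperm(array(vec, c(bands, samples, lines)), c(3, 2, 1)))
    if (!is.null(h[["wavelength"]])) {
        wl <- gsub("[{}]", "", h[["wavelength"]])
        wl <- as.numeric(strsplit(wl, ",")[[1]])
        axis <- spectralAxis(wavelengths = wl)
    } else {
        warning("ENVI header carries no wavelength list; ",
                "using band indices as the spectral axis")
        axis <- spectralAxis(wavelengths = seq_len(bands))
    }
    hyperCube(a, axis = axis, kind = "raw", provenance = rawPath)
}

#' Export a mean spectrum as CSV
#'
#' Two columns: `wavelength` (nm) and `reflectance`.
#'
#' @param spectrum numeric vector as returned by [meanSpectrum()].
#' @param axis the matching [SpectralAxis-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeSpectrumCSV <- function(spectrum, axis, path) {
    utils::write.csv(
        data.frame(wavelength = axis@wavelengths, reflectance = spectrum),
        path, row.names = FALSE)
    invisible(path)
}
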