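rawCube <- function(data, b = dim(data)[3]) {
    hyperCube(data, spectralAxis(wavelengths = seq_len(b)), kind = "raw")
}

test_that("radiometric correction reproduces the defining ratios", {
    d <- c(4, 5, 3)
    w <- matrix(200, d[1], d[2]); k <- matrix(40, d[1], d[2])
    refs <- referenceFrames(w, k)
    expect_equal(cubeData(radiometricCorrect(rawCube(array(200, d)), refs)),
                 array(1, d))
    expect_equal(cubeData(radiometricCorrect(rawCube(array(40, d)), refs)),
                 array(0, d))
    expect_equal(cubeData(radiometricCorrect(rawCube(array(120, d)), refs)),
                 array(0.5, d))
})

test_that("correction is invariant to a joint intensity rescaling", {
    set.seed(9)
    d <- c(6, 6, 4)
    raw <- array(runif(prod(d), 50, 180), d)
    w <- matrix(runif(36, 190, 220), 6, 6)
    k <- matrix(runif(36, 5, 15), 6, 6)
    r1 <- radiometricCorrect(rawCube(raw), referenceFrames(w, k))
    r2 <- radiometricCorrect(rawCube(raw * 3.7),
                             referenceFrames(w * 3.7, k * 3.7))
    expect_equal(cubeData(r1), cubeData(r2), tolerance = 1e-12)
})

test_that("correction refuses bands where white does not exceed dark", {
    d <- c(3, 3, 4)
    w <- array(100, d); w[, , 3] <- 5       # band 3 broken
    k <- array(10, d)
    expect_error(
        radiometricCorrect(rawCube(array(50, d)), referenceFrames(w, k)),
        "band\\(s\\) 3")
})

test_that("per-band reference cubes are honoured", {
    d <- c(2, 2, 2)
    w <- array(c(100, 100, 100, 100, 300, 300, 300, 300), d)
    k <- array(0, d)
    raw <- array(c(rep(50, 4), rep(150, 4)), d)
    out <- radiometricCorrect(rawCube(raw), referenceFrames(w, k))
    expect_equal(as.numeric(cubeData(out)), rep(0.5, 8))
})

test_that("meanSpectrum averages exactly over the ROI", {
    cc <- constantCube(0.37)
    expect_equal(meanSpectrum(cc, roi(0, 0, 8, 8)), rep(0.37, 6))
    # single-pixel ROI returns that pixel's spectrum
    arr <- array(seq_len(8 * 8 * 6) / 100, c(8, 8, 6))
    cube <- hyperCube(arr, spectralAxis(wavelengths = 1:6),
                      kind = "corrected")
    expect_equal(meanSpectrum(cube, roi(2, 3, 1, 1)), arr[3, 4, ])
    # checkerboard of a and b averages to (a+b)/2
    chk <- array(0, c(4, 4, 2))
    pattern <- outer(1:4, 1:4, function(i, j) (i + j) %% 2)
    chk[, , 1] <- ifelse(pattern == 1, 0.2, 0.6)
    chk[, , 2] <- ifelse(pattern == 1, 0.1, 0.9)
    cube <- hyperCube(chk, spectralAxis(wavelengths = 1:2), kind = "corrected")
    expect_equal(meanSpectrum(cube, roi(0, 0, 4, 4)), c(0.4, 0.5))
    expect_error(meanSpectrum(cube, roi(2, 2, 4, 4)), "beyond")
})

test_that("meanSpectrum commutes with correction under constant references", {
    set.seed(10)
    d <- c(10, 10, 5)
    raw <- rawCube(array(runif(prod(d), 60, 150), d))
    refs <- referenceFrames(matrix(180, 10, 10), matrix(20, 10, 10))
    r <- roi(1, 2, 5, 4)
    a <- meanSpectrum(radiometricCorrect(raw, refs), r)
    b <- (meanSpectrum(raw, r) - 20) / (180 - 20)
    expect_equal(a, b, tolerance = 1e-12)
})

# -- automatic ROI ---------------------------------------------------------

ellipseCube <- function(h = 60, w = 60, center = c(0.5, 0.5), b = 8,
                        bright = 0.7, dark = 0.03) {
    rr <- matrix(seq_len(h), h, w)
    cc <- matrix(seq_len(w), h, w, byrow = TRUE)
    mask <- ((rr - center[1] * h) / (0.35 * h))^2 +
            ((cc - center[2] * w) / (0.28 * w))^2 <= 1
    arr <- array(dark, c(h, w, b))
    for (k in seq_len(b)) arr[, , k][mask] <- bright
    list(cube = hyperCube(arr, spectralAxis(wavelengths = seq(400, 1000,
                                                              length.out = b)),
                          kind = "corrected"),
         mask = mask)
}

test_that("autoROI centres on a centred fruit", {
    ec <- ellipseCube()
    r <- autoROI(ec$cube, size = 10)
    expect_equal(r@rowOffset + 5, 30, tolerance = 2)
    expect_equal(r@colOffset + 5, 30, tolerance = 2)
    expect_identical(autoROI(ec$cube, size = 10), r)  # deterministic
})

test_that("autoROI tracks the mask centroid, not the image centre", {
    ec <- ellipseCube(center = c(0.38, 0.62))
    r <- autoROI(ec$cube, size = 8)
    ctr <- which(ec$mask, arr.ind = TRUE)
    expect_equal(r@rowOffset + 4, mean(ctr[, 1]), tolerance = 1.5)
    expect_equal(r@colOffset + 4, mean(ctr[, 2]), tolerance = 1.5)
})

test_that("autoROI validates size against cube and mask", {
    ec <- ellipseCube(h = 30, w = 30)
    expect_error(autoROI(ec$cube, size = 40), "exceeds")
    small <- ellipseCube(h = 60, w = 60)
    small$cube@data[, , ] <- 0.03          # no fruit at all -> constant
    expect_error(autoROI(small$cube, size = 10), "constant")
})

test_that("defaultROISize reproduces the full-scale ROI proportion", {
    full <- hyperCube(array(0, c(1040, 1392, 2)),
                      spectralAxis(wavelengths = 1:2))
    expect_equal(defaultROISize(full), 110L)
    desk <- hyperCube(array(0, c(64, 64, 2)), spectralAxis(wavelengths = 1:2))
    expect_equal(defaultROISize(desk), 7L)
})

# -- ENVI round trips ------------------------------------------------------

test_that("ENVI write/read round-trips bit-identically in every interleave", {
    set.seed(11)
    cube <- hyperCube(array(runif(9 * 7 * 5), c(9, 7, 5)),
                      spectralAxis(wavelengths = seq(400, 1000,
                                                     length.out = 5)))
    ref <- NULL
    for (il in c("bsq", "bil", "bip")) {
        base <- file.path(tempdir(), paste0("cube_", il))
        writeENVI(cube, base, interleave = il)
        back <- readENVI(base)
        expect_identical(cubeData(back), cubeData(cube))
        expect_equal(wavelengths(back), wavelengths(cube))
        if (is.null(ref)) ref <- cubeData(back)
        else expect_identical(cubeData(back), ref)  # interleave-independent
    }
})

test_that("ENVI failure modes are reported distinctly", {
    set.seed(12)
    cube <- hyperCube(array(runif(4 * 4 * 3), c(4, 4, 3)),
                      spectralAxis(wavelengths = 1:3))
    base <- file.path(tempdir(), "envi_bad")
    writeENVI(cube, base)

    hdr <- readLines(paste0(base, ".hdr"))
    # missing wavelengths: degraded axis + warning
    writeLines(hdr[!grepl("wavelength", hdr)], paste0(base, ".hdr"))
    expect_warning(b <- readENVI(base), "no wavelength list")
    expect_equal(wavelengths(b), 1:3)

    # malformed header: required key missing
    writeLines(hdr[!grepl("^bands", hdr)], paste0(base, ".hdr"))
    expect_error(readENVI(base), "malformed ENVI header")

    # unknown interleave
    writeLines(sub("interleave = bsq", "interleave = weird", hdr),
               paste0(base, ".hdr"))
    expect_error(readENVI(base), "interleave mismatch")

    # truncated payload
    writeLines(hdr, paste0(base, ".hdr"))
    raw <- readBin(paste0(base, ".raw"), "raw",
                   file.info(paste0(base, ".raw"))$size)
    writeBin(raw[1:100], paste0(base, ".raw"))
    expect_error(readENVI(base), "truncated")

    # missing magic
    writeLines(c("NOPE", hdr[-1]), paste0(base, ".hdr"))
    expect_error(readENVI(base), "magic")
})

test_that("float32 ENVI keeps data to single precision", {
    cube <- hyperCube(array(runif(2 * 2 * 2), c(2, 2, 2)),
                      spectralAxis(wavelengths = 1:2))
    base <- file.path(tempdir(), "envi_f32")
    writeENVI(cube, base, dataType = 4L)
    expect_equal(cubeData(readENVI(base)), cubeData(cube), tolerance = 1e-6)
})
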