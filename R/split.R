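#' Bundle spectra and response into a dataset
#'
#' @param X n x p matrix of mean reflectance spectra.
#' @param y numeric response (the composite quality index), length n.
#' @param axis a [SpectralAxis-class] with p bands.
#' @return a [SpectralDataset-class] with unassigned split labels.
#' @export
spectralDataset <- function(X, y, axis = spectralAxis(wavelengths = seq_len(ncol(X)))) {
    new("SpectralDataset", X = as.matrix(X), y = as.numeric(y), axis = axis,
        split = rep(NA_character_, nrow(X)))
}

#' @rdname spectralDataset
#' @param ds a `SpectralDataset`.
#' @export
calibrationIdx <- function(ds) which(ds@split == "calibration")

#' @rdname spectralDataset
#' @export
predictionIdx <- function(ds) which(ds@split == "prediction")

setMethod("show", "SpectralDataset", function(object) {
    cat(sprintf("SpectralDataset: %d samples x %d bands", nrow(object@X),
                ncol(object@X)))
    if (!anyNA(object@split))
        cat(sprintf(" (%d calibration / %d prediction)",
                    sum(object@split == "calibration"),
                    sum(object@split == "prediction")))
    cat("\n")
})

# Internal: the calibration block of a split dataset; errors when selectors
# are invoked before splitting, which is the leakage guard's anchor.
calBlock <- function(ds) {
    idx <- calibrationIdx(ds)
    if (!length(idx))
        stop("dataset has no calibration split; run spxySplit() first")
    list(X = ds@X[idx, , drop = FALSE], y = ds@y[idx])
}

#' SPXY calibration/prediction partitioning
#'
#' Kennard-Stone-style greedy max-min selection on the joint
#' predictor-response distance
#' \deqn{d(i,j) = d_X(i,j)/\max d_X + d_y(i,j)/\max d_y}
#' (Euclidean in X, absolute difference in y), so the calibration set covers
#' both the spectral and the response space. The two most distant samples
#' are seeded first; each following pick maximises the minimal joint
#' distance to the already-selected set. Deterministic; ties break towards
#' the lowest sample index.
#'
#' @param ds a [SpectralDataset-class].
#' @param calibrationFraction fraction assigned to calibration
#'   (default 0.8); calibration size is `round(fraction * n)`.
#' @return the dataset with `split` labels filled.
#' @export
spxySplit <- function(ds, calibrationFraction = 0.8) {
    n <- nrow(ds@X)
    if (n < 5L) stop("SPXY needs at least 5 samples")
    nCal <- as.integer(round(calibrationFraction * n))
    nCal <- min(max(nCal, 2L), n - 1L)
    dX <- as.matrix(stats::dist(ds@X))
    dY <- abs(outer(ds@y, ds@y, "-"))
    D <- dX / max(dX) + dY / max(dY)
    first <- which(D == max(D), arr.ind = TRUE)[1, ]
    sel <- sort(as.integer(first))[1:2]
    minD <- pmin(D[, sel[1]], D[, sel[2]])
    while (length(sel) < nCal) {
        minD[sel] <- -Inf
        nxt <- which.max(minD)          # which.max takes the first maximum
        sel <- c(sel, nxt)
        minD <- pmin(minD, D[, nxt])
    }
    split <- rep("prediction", n)
    split[sel] <- "calibration"
    ds@split <- split
    validObject(ds)
    ds
}
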