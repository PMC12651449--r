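#' Evaluation metrics for a model on a sample set
#'
#' `r2 = 1 - SS_res/SS_tot` against the evaluated set's own mean;
#' `rmse = sqrt(mean((obs - pred)^2))`; `rpd = SD(obs)/rmse` (population
#' denominator), attached for the prediction set and reported as `Inf` when
#' the fit is exact.
#'
#' @param obs reference values.
#' @param pred model predictions.
#' @param withRPD attach the relative predictive deviation.
#' @return list with `r2`, `rmse` and optionally `rpd`.
#' @export
evalMetrics <- function(obs, pred, withRPD = FALSE) {
    ssRes <- sum((obs - pred)^2)
    ssTot <- sum((obs - mean(obs))^2)
    out <- list(r2 = 1 - ssRes / ssTot, rmse = sqrt(ssRes / length(obs)))
    if (withRPD) out$rpd <- if (out$rmse == 0) Inf else popSD(obs) / out$rmse
    out
}

#' Evaluate a fitted model on one side of the split
#'
#' @param fit a [FitResult-class].
#' @param ds a split [SpectralDataset-class] (full spectra; the model's own
#'   band subset is applied internally).
#' @param which `"calibration"` or `"prediction"`.
#' @return the updated [FitResult-class] with the metrics slot filled.
#' @export
evaluateModel <- function(fit, ds, which = c("prediction", "calibration")) {
    which <- match.arg(which)
    idx <- if (which == "calibration") calibrationIdx(ds) else predictionIdx(ds)
    obs <- ds@y[idx]
    pred <- predict(fit, ds@X[idx, , drop = FALSE])
    m <- evalMetrics(obs, pred, withRPD = which == "prediction")
    slot(fit, which) <- m
    fit
}

newFitResult <- function(kind, fit, bands,
                         xCenter = numeric(0), xScale = numeric(0),
                         yCenter = 0, yScale = 1,
                         history = data.frame()) {
    new("FitResult", kind = kind, fit = fit, bands = as.integer(bands),
        xCenter = xCenter, xScale = xScale, yCenter = yCenter,
        yScale = yScale, history = history,
        calibration = list(), prediction = list())
}

setMethod("show", "FitResult", function(object) {
    cat(sprintf("FitResult (%s): %d input band(s)\n", object@kind,
                length(object@bands)))
    fmt <- function(m, tag) if (length(m))
        cat(sprintf("  %s: R2 %.4f, RMSE %.4f%s\n", tag, m$r2, m$rmse,
                    if (!is.null(m$rpd)) sprintf(", RPD %.4f", m$rpd) else ""))
    fmt(object@calibration, "calibration")
    fmt(object@prediction, "prediction ")
})

# Restrict a full-spectrum matrix to the model's bands.
bandMatrix <- function(fit, X) {
    X <- as.matrix(X)
    if (ncol(X) == length(fit@bands)) X
    else X[, fit@bands, drop = FALSE]
}

#' Predict the quality index from spectra
#'
#' @param object a [FitResult-class].
#' @param newdata spectra matrix: either full-spectrum (the model's band
#'   subset is applied) or already restricted to the model's bands.
#' @param ... unused.
#' @return numeric predictions.
#' @export
setMethod("predict", "FitResult", function(object, newdata, ...) {
    X <- bandMatrix(object, newdata)
    switch(object@kind,
        plsr = simplsPredict(object@fit, X, object@fit$ncompSelected),
        rf = {
            colnames(X) <- paste0("b", object@bands)
            as.numeric(predict(object@fit, X))
        },
        cnn = {
            Z <- sweep(sweep(X, 2, object@xCenter), 2, object@xScale, "/")
            cnnForward(object@fit, Z, training = FALSE)$pred *
                object@yScale + object@yCenter
        },
        stop("unknown model kind ", object@kind))
})

#' Partial least squares regression with CV-chosen components
#'
#' SIMPLS fit on the calibration spectra; the number of latent variables is
#' the minimiser of the k-fold cross-validated RMSE over `1..maxComp`.
#'
#' @param ds a split [SpectralDataset-class].
#' @param bands a [BandSubset-class] (default: full spectrum).
#' @param maxComp largest latent-variable count considered (default 15).
#' @param folds cross-validation folds (default 10).
#' @return a [FitResult-class] with calibration metrics filled.
#' @export
fitPLSR <- function(ds, bands = fullBands(ds), maxComp = 15L, folds = 10L) {
    cal <- calBlock(ds)
    X <- cal$X[, bands@indices, drop = FALSE]
    y <- cal$y
    cvr <- plsRMSECV(X, y, maxComp, folds)
    ncompSel <- which.min(cvr)
    fit <- simplsFit(X, y, ncompSel)
    fit$ncompSelected <- min(ncompSel, fit$ncomp)
    out <- newFitResult("plsr", fit, bands@indices,
                        history = data.frame(ncomp = seq_along(cvr),
                                             rmsecv = cvr))
    out@calibration <- evalMetrics(y, simplsPredict(fit, X, fit$ncompSelected))
    out
}

#' Random-forest regression
#'
#' 100-tree ensemble with a minimum leaf size of 8, seeded for
#' reproducibility.
#'
#' @param ds a split [SpectralDataset-class].
#' @param bands a [BandSubset-class] (default: full spectrum).
#' @param nTrees trees in the ensemble (default 100).
#' @param minLeaf minimum terminal-node size (default 8).
#' @param seed integer seed.
#' @return a [FitResult-class] with calibration metrics filled.
#' @export
fitRF <- function(ds, bands = fullBands(ds), nTrees = 100L, minLeaf = 8L,
                  seed = 1L) {
    cal <- calBlock(ds)
    X <- cal$X[, bands@indices, drop = FALSE]
    colnames(X) <- paste0("b", bands@indices)
    y <- cal$y
    rf <- withSeed(seed,
        randomForest::randomForest(x = X, y = y, ntree = nTrees,
                                   nodesize = minLeaf))
    out <- newFitResult("rf", rf, bands@indices)
    out@calibration <- evalMetrics(y, as.numeric(predict(rf, X)))
    out
}
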