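bandSubset <- function(method, indices, axis, diagnostics = list()) {
    indices <- sort(unique(as.integer(indices)))
    new("BandSubset", method = method, indices = indices,
        wavelengths = axis@wavelengths[indices], diagnostics = diagnostics)
}

setMethod("show", "BandSubset", function(object) {
    cat(sprintf("BandSubset (%s): %d band(s)\n", object@method,
                length(object@indices)))
    if (length(object@indices))
        cat("  ", paste(sprintf("%.0f", object@wavelengths), collapse = ", "),
            "nm\n")
})

#' Full-spectrum pseudo-subset
#'
#' @param ds a [SpectralDataset-class].
#' @return a [BandSubset-class] covering every band.
#' @export
fullBands <- function(ds) {
    bandSubset("full", seq_len(ncol(ds@X)), ds@axis)
}

# Safe sampling from a vector of any length (sample() would interpret a
# length-1 integer vector as 1:n).
resample <- function(x, size, replace = FALSE, prob = NULL) {
    x[sample.int(length(x), size, replace = replace, prob = prob)]
}

# Successive-projection chain from a starting column: repeatedly add the
# column with the largest norm after projection onto the orthogonal
# complement of the selected columns (rank-1 residual updates). Stops early
# when only numerically exhausted (collinear) columns remain.
spaChain <- function(Xc, start, maxBands) {
    R <- Xc
    chain <- integer(0)
    nxt <- start
    for (m in seq_len(maxBands)) {
        v <- R[, nxt]
        nv <- sum(v^2)
        if (nv < 1e-20) break
        chain <- c(chain, nxt)
        R <- R - (v / nv) %*% crossprod(v, R)
        if (m == maxBands) break
        norms <- colSums(R^2)
        norms[chain] <- -Inf
        norms[norms < 1e-20] <- -Inf
        if (all(!is.finite(norms))) break
        nxt <- which.max(norms)
    }
    chain
}

# Ordinary least-squares RMSE of y on the selected columns (with intercept).
olsRMSE <- function(X, y, idx) {
    fit <- stats::lm.fit(cbind(1, X[, idx, drop = FALSE]), y)
    sqrt(mean(fit$residuals^2))
}

#' Successive projections algorithm (SPA)
#'
#' Forward selection of minimally collinear bands. For every starting band a
#' chain is grown by repeatedly adding the band whose column has the largest
#' norm after projection onto the orthogonal complement of the already
#' selected columns; each chain prefix is scored by the calibration RMSE of
#' an ordinary least-squares fit. The returned subset is the shortest chain
#' whose RMSE is not significantly worse than the global minimum under an
#' F-test (`F = RMSE^2 / RMSE_min^2`) at level `alpha`.
#'
#' Runs strictly on the calibration rows.
#'
#' @param ds a split [SpectralDataset-class].
#' @param maxBands longest chain considered (must stay below the calibration
#'   sample count).
#' @param alpha F-test significance level (default 0.25).
#' @return a [BandSubset-class]; diagnostics carry the per-size minimum RMSE
#'   path (`rmsePath`), the chosen size and the F-test cut-off.
#' @export
spaSelect <- function(ds, maxBands = 25L, alpha = 0.25) {
    cal <- calBlock(ds)
    X <- cal$X; y <- cal$y
    n <- nrow(X); p <- ncol(X)
    maxBands <- as.integer(maxBands)
    if (maxBands >= n)
        stop("maxBands must be smaller than the calibration sample count ",
             "(rank limit)")
    maxBands <- min(maxBands, p)
    Xc <- scale(X, center = TRUE, scale = FALSE)
    bestRMSE <- rep(Inf, maxBands)
    bestChain <- vector("list", maxBands)
    for (start in seq_len(p)) {
        chain <- spaChain(Xc, start, maxBands)
        for (m in seq_along(chain)) {
            r <- olsRMSE(X, y, chain[seq_len(m)])
            if (r < bestRMSE[m]) {
                bestRMSE[m] <- r
                bestChain[[m]] <- chain[seq_len(m)]
            }
        }
    }
    sizes <- which(is.finite(bestRMSE))
    mMin <- sizes[which.min(bestRMSE[sizes])]
    rmin <- bestRMSE[mMin]
    chosen <- mMin
    for (m in sizes) {
        # RMSEs within numerical noise of the minimum count as equal (the
        # ratio of two ~1e-16 residuals is meaningless)
        Fstat <- if (bestRMSE[m] - rmin <= 1e-10 * (1 + rmin)) 1
                 else bestRMSE[m]^2 / max(rmin, 1e-300)^2
        Fcrit <- stats::qf(1 - alpha, n - m, n - mMin)
        if (Fstat <= Fcrit) { chosen <- m; break }
    }
    bandSubset("spa", bestChain[[chosen]], ds@axis,
               diagnostics = list(rmsePath = bestRMSE, size = chosen,
                                  minSize = mMin, minRMSE = rmin,
                                  alpha = alpha))
}

#' Competitive adaptive reweighted sampling (CARS)
#'
#' Monte-Carlo PLS-coefficient-weighted band elimination. In each of
#' `nRuns` runs a random `mcFraction` of the calibration samples is used to
#' fit a PLS model on the surviving bands; the exponentially decreasing
#' retention schedule `r(i) = a e^{-k i}` (fixed by `r(1) = 1`,
#' `r(nRuns) = 2/p`) forces the retained count down; the top bands by
#' absolute PLS coefficient survive the forced step, followed by adaptive
#' reweighted sampling (weighted bootstrap on the survivors). Every run's
#' retained set is scored by k-fold PLS RMSECV on the full calibration set;
#' the set with minimal RMSECV wins.
#'
#' Runs strictly on the calibration rows.
#'
#' @param ds a split [SpectralDataset-class].
#' @param nRuns Monte-Carlo iterations (default 50).
#' @param mcFraction calibration fraction sampled per run (default 0.8).
#' @param folds RMSECV folds (default 5).
#' @param maxComp PLS component cap; the count is chosen by inner CV.
#' @param seed integer seed.
#' @return a [BandSubset-class]; diagnostics carry the retained-count and
#'   RMSECV paths and the winning run.
#' @export
carsSelect <- function(ds, nRuns = 50L, mcFraction = 0.8, folds = 5L,
                       maxComp = 10L, seed = 1L) {
    cal <- calBlock(ds)
    X <- cal$X; y <- cal$y
    n <- nrow(X); p <- ncol(X)
    stopifnot(p >= 2L)
    kDecay <- log(p / 2) / (nRuns - 1)
    aDecay <- exp(kDecay)
    withSeed(seed, {
        surviving <- seq_len(p)
        counts <- integer(0); cvPath <- numeric(0)
        sets <- vector("list", nRuns)
        for (i in seq_len(nRuns)) {
            keepN <- max(2L, min(length(surviving),
                                 as.integer(round(aDecay * exp(-kDecay * i) * p))))
            mc <- sample(n, max(2L, round(mcFraction * n)))
            Xmc <- X[mc, surviving, drop = FALSE]
            # components by inner CV: an overfit weight model concentrates
            # the coefficient mass and collapses the reweighted sampling
            cvr <- plsRMSECV(Xmc, y[mc], min(maxComp, length(surviving)),
                             folds)
            fit <- simplsFit(Xmc, y[mc], which.min(cvr))
            w <- abs(fit$coef[, fit$ncomp])
            forced <- surviving[order(w, decreasing = TRUE)[seq_len(keepN)]]
            wForced <- w[match(forced, surviving)]
            if (all(wForced == 0)) wForced <- wForced + 1
            ars <- unique(resample(forced, size = keepN, replace = TRUE,
                                   prob = wForced))
            if (length(ars) < 2L) {
                warning("CARS run ", i, " left fewer than 2 bands; truncated")
                break
            }
            surviving <- sort(ars)
            cvr <- plsRMSECV(X[, surviving, drop = FALSE], y,
                             min(maxComp, length(surviving)), folds)
            sets[[i]] <- surviving
            counts <- c(counts, length(surviving))
            cvPath <- c(cvPath, min(cvr))
        }
        best <- which.min(cvPath)
        bandSubset("cars", sets[[best]], ds@axis,
                   diagnostics = list(retainedCounts = counts,
                                      rmsecvPath = cvPath, bestRun = best))
    })
}

#' Random frog band selection
#'
#' An MCMC-style chain over band subsets: each iteration proposes a new
#' subset whose size is drawn from a normal distribution around the current
#' size (grown with random additions, shrunk with random deletions, or a
#' single swap at equal size), accepts improvements in k-fold PLS RMSECV
#' outright and worse candidates with probability
#' `eta * RMSECV / RMSECV_candidate`. Each band's selection probability is
#' its inclusion frequency along the chain; bands at or above `threshold`
#' are returned.
#'
#' Runs strictly on the calibration rows.
#'
#' @param ds a split [SpectralDataset-class].
#' @param nIterations chain length (default 1000).
#' @param threshold selection-probability cut-off in (0, 1) (default 0.40).
#' @param initSize initial subset size (default 10).
#' @param proposalSD proposal SD as a fraction of the current size (0.3).
#' @param eta acceptance damping for worse candidates (default 0.1).
#' @param folds RMSECV folds (default 5).
#' @param maxComp PLS component cap.
#' @param seed integer seed.
#' @return a [BandSubset-class]; diagnostics carry the per-band selection
#'   probabilities and the RMSECV trace.
#' @export
rfrogSelect <- function(ds, nIterations = 1000L, threshold = 0.40,
                        initSize = 10L, proposalSD = 0.3, eta = 0.1,
                        folds = 5L, maxComp = 10L, seed = 1L) {
    if (threshold <= 0 || threshold >= 1)
        stop("threshold must lie strictly inside (0, 1)")
    cal <- calBlock(ds)
    X <- cal$X; y <- cal$y
    p <- ncol(X)
    cvErr <- function(idx) min(plsRMSECV(X[, idx, drop = FALSE], y,
                                         min(maxComp, length(idx)), folds))
    withSeed(seed, {
        current <- sort(sample(p, min(initSize, p)))
        errCur <- cvErr(current)
        counts <- numeric(p)
        errPath <- numeric(nIterations)
        for (i in seq_len(nIterations)) {
            size <- length(current)
            newSize <- max(1L, min(p, as.integer(round(
                stats::rnorm(1, size, proposalSD * size)))))
            if (newSize > size) {
                pool <- setdiff(seq_len(p), current)
                cand <- sort(c(current, resample(pool, min(newSize - size,
                                                           length(pool)))))
            } else if (newSize < size) {
                cand <- sort(resample(current, newSize))
            } else {
                pool <- setdiff(seq_len(p), current)
                cand <- if (length(pool)) sort(c(resample(current, size - 1L),
                                                 resample(pool, 1L)))
                        else current
            }
            errCand <- cvErr(cand)
            accept <- errCand <= errCur ||
                stats::runif(1) < eta * errCur / errCand
            if (accept) { current <- cand; errCur <- errCand }
            counts[current] <- counts[current] + 1
            errPath[i] <- errCur
        }
        probs <- counts / nIterations
        idx <- which(probs >= threshold)
        if (!length(idx))
            warning("no band reaches the selection-probability threshold ",
                    threshold, "; empty subset")
        bandSubset("rfrog", idx, ds@axis,
                   diagnostics = list(probabilities = probs,
                                      rmsecvPath = errPath,
                                      threshold = threshold))
    })
}
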