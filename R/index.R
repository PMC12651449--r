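qualityParams <- c("ssc", "firmness", "L", "a", "b", "chroma")

# Extract the quality-parameter matrix from a table, in canonical order.
qualityMatrix <- function(table, params = qualityParams) {
    miss <- setdiff(params, names(table))
    if (length(miss))
        stop("quality table lacks column(s): ", paste(miss, collapse = ", "))
    as.matrix(table[params])
}

#' Pearson correlation matrix of the quality parameters
#'
#' @param table a quality table (see [simulateQualityTable()]) or a numeric
#'   matrix with one column per parameter.
#' @param params columns to correlate, in order.
#' @return symmetric p x p matrix with unit diagonal. Constant columns are
#'   flagged with a warning and yield `NA` entries.
#' @export
pearsonMatrix <- function(table, params = qualityParams) {
    M <- if (is.matrix(table)) table else qualityMatrix(table, params)
    sds <- apply(M, 2, stats::sd)
    if (any(sds == 0))
        warning("constant column(s) ",
                paste(colnames(M)[sds == 0], collapse = ", "),
                ": correlations undefined (NA)")
    suppressWarnings(stats::cor(M))
}

#' Z-score normalisation
#'
#' Maps each column to mean 0, SD 1 (the common scale used before factor
#' analysis). Idempotent up to floating point.
#'
#' @param x numeric matrix or a quality table.
#' @param params columns when `x` is a table.
#' @return matrix of standardised columns.
#' @export
zscoreNormalize <- function(x, params = qualityParams) {
    M <- if (is.matrix(x)) x else qualityMatrix(x, params)
    sds <- apply(M, 2, stats::sd)
    if (any(sds == 0))
        stop("cannot z-score constant column(s): ",
             paste(colnames(M)[sds == 0], collapse = ", "))
    scale(M)[, , drop = FALSE]
}

#' Kaiser-Meyer-Olkin sampling adequacy
#'
#' \deqn{KMO = \sum_{i \ne j} r_{ij}^2 / (\sum_{i \ne j} r_{ij}^2 +
#'   \sum_{i \ne j} q_{ij}^2)}
#' where q are the anti-image partial correlations obtained from the inverse
#' correlation matrix. Values above 0.5 conventionally indicate that a
#' dataset is adequate for factor analysis.
#'
#' @param corr correlation matrix (or a quality table, correlated first).
#' @return scalar in [0, 1]. A singular correlation matrix falls back to the
#'   Moore-Penrose pseudo-inverse with a warning.
#' @export
kmoMeasure <- function(corr) {
    R <- if (is.matrix(corr) && nrow(corr) == ncol(corr)) corr
         else pearsonMatrix(corr)
    Ri <- tryCatch(solve(R), error = function(e) {
        warning("singular correlation matrix; using pseudo-inverse for the ",
                "anti-image correlations")
        MASS::ginv(R)
    })
    Q <- -Ri / sqrt(outer(diag(Ri), diag(Ri)))
    diag(Q) <- 0
    R0 <- R; diag(R0) <- 0
    sum(R0^2) / (sum(R0^2) + sum(Q^2))
}

#' Bartlett's test of sphericity
#'
#' Tests whether a correlation matrix deviates from the identity:
#' \deqn{\chi^2 = -(n - 1 - (2p + 5)/6) \ln \det R, \quad df = p(p-1)/2.}
#'
#' @param corr p x p correlation matrix.
#' @param n number of samples behind the matrix.
#' @return named numeric vector `(chi2, df, p)`.
#' @export
bartlettSphericity <- function(corr, n) {
    p <- ncol(corr)
    detR <- det(corr)
    chi2 <- if (detR <= 0) Inf else
        -(n - 1 - (2 * p + 5) / 6) * log(detR)
    df <- p * (p - 1) / 2
    c(chi2 = chi2, df = df,
      p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Factor analysis of the quality parameters
#'
#' Principal-component extraction on the correlation matrix: loadings are
#' eigenvectors scaled by the square root of their eigenvalues; the smallest
#' number of factors whose cumulative explained variance reaches
#' `varianceThreshold` percent is retained; the retained loadings are
#' varimax-rotated (with Kaiser normalisation) and each column's sign is
#' flipped so its largest-magnitude variable loads positively.
#'
#' @param x a quality table, a data matrix, or a p x p correlation matrix.
#' @param n sample count (required for Bartlett's test when `x` is already a
#'   correlation matrix).
#' @param varianceThreshold cumulative variance cut-off, percent (default 80).
#' @param params columns when `x` is a table.
#' @return a [FactorModel-class] carrying the adequacy diagnostics,
#'   eigenstructure and rotated loadings.
#' @export
factorAnalysis <- function(x, n = NA_integer_, varianceThreshold = 80,
                           params = qualityParams) {
    if (is.matrix(x) && nrow(x) == ncol(x) &&
        all(abs(diag(x) - 1) < 1e-8)) {
        R <- x
    } else {
        M <- if (is.matrix(x)) x else qualityMatrix(x, params)
        n <- nrow(M)
        R <- pearsonMatrix(M)
    }
    if (anyNA(R)) stop("correlation matrix contains NA")
    if (any(abs(R - t(R)) > 1e-8)) stop("correlation matrix is not symmetric")
    e <- eigen(R, symmetric = TRUE)
    if (min(e$values) < -1e-8)
        stop("correlation matrix is not positive semi-definite ",
             sprintf("(smallest eigenvalue %.3g)", min(e$values)))
    p <- ncol(R)
    cumvar <- cumsum(e$values) / p * 100
    k <- which(cumvar >= varianceThreshold)[1]
    if (is.na(k)) k <- p
    load <- e$vectors[, seq_len(k), drop = FALSE] %*%
        diag(sqrt(pmax(e$values[seq_len(k)], 0)), k)
    rotation <- "none"
    if (k >= 2L) {
        load <- stats::varimax(load, normalize = TRUE)$loadings[, , drop = FALSE]
        load <- matrix(as.numeric(load), nrow = p)
        rotation <- "varimax"
    }
    # sign convention: per factor, the variable with the largest |loading|
    # loads positively
    for (j in seq_len(k)) {
        i <- which.max(abs(load[, j]))
        if (load[i, j] < 0) load[, j] <- -load[, j]
    }
    dimnames(load) <- list(colnames(R), paste0("factor", seq_len(k)))
    bart <- if (is.na(n)) c(chi2 = NA_real_, df = NA_real_, p = NA_real_)
            else bartlettSphericity(R, n)
    new("FactorModel", correlation = R, kmo = kmoMeasure(R),
        bartlett = bart, eigenvalues = e$values,
        cumulativeVariance = cumvar, loadings = load,
        retainedK = as.integer(k), rotation = rotation)
}

setMethod("show", "FactorModel", function(object) {
    cat(sprintf("FactorModel: %d variables, %d retained factor(s) (%s)\n",
                ncol(object@correlation), object@retainedK, object@rotation))
    cat(sprintf("  KMO %.3f | Bartlett chi2 %.1f (df %d, p %.3g)\n",
                object@kmo, object@bartlett["chi2"], object@bartlett["df"],
                object@bartlett["p"]))
    cat(sprintf("  cumulative variance: %s%%\n",
                paste(sprintf("%.1f", object@cumulativeVariance), collapse = " ")))
    print(round(object@loadings, 3))
})

#' Loading-based parameter selection
#'
#' A parameter is selected when its largest absolute loading on a retained
#' factor exceeds `loadingThreshold` and it is not cross-loaded. A parameter
#' counts as cross-loaded when its second-largest absolute loading is at
#' least `crossMin` *and* lies within `crossGap` of the largest -- a rule
#' that excludes a variable split almost evenly between factors while
#' keeping variables with one clearly dominant loading. Factors on which no
#' parameter is selected are dropped.
#'
#' @param model a [FactorModel-class] (or a bare loading matrix).
#' @param loadingThreshold minimum dominant absolute loading (default 0.5).
#' @param crossMin secondary-loading magnitude that can disqualify (0.4).
#' @param crossGap maximum dominant/secondary gap that disqualifies (0.2).
#' @return a list: `selected` (parameter names), `dominantFactor`,
#'   `dominantSign`, `crossLoaded` (excluded parameters), `retainedFactors`
#'   (factors carrying at least one selected parameter).
#' @export
selectParameters <- function(model, loadingThreshold = 0.5,
                             crossMin = 0.4, crossGap = 0.2) {
    L <- if (is(model, "FactorModel")) model@loadings else as.matrix(model)
    if (is.null(rownames(L))) rownames(L) <- paste0("V", seq_len(nrow(L)))
    res <- lapply(seq_len(nrow(L)), function(i) {
        al <- abs(L[i, ])
        o <- order(al, decreasing = TRUE)
        dominant <- al[o[1]]
        second <- if (length(al) > 1) al[o[2]] else 0
        cross <- second >= crossMin && (dominant - second) < crossGap
        list(pass = dominant > loadingThreshold && !cross,
             cross = dominant > loadingThreshold && cross,
             factor = o[1], sign = sign(L[i, o[1]]))
    })
    pass <- vapply(res, `[[`, logical(1), "pass")
    if (!any(pass))
        message("no parameter exceeds the loading threshold; empty selection")
    selected <- rownames(L)[pass]
    dominantFactor <- vapply(res, `[[`, numeric(1), "factor")[pass]
    names(dominantFactor) <- selected
    dominantSign <- vapply(res, `[[`, numeric(1), "sign")[pass]
    names(dominantSign) <- selected
    list(selected = selected,
         dominantFactor = dominantFactor,
         dominantSign = dominantSign,
         crossLoaded = rownames(L)[vapply(res, `[[`, logical(1), "cross")],
         retainedFactors = sort(unique(unname(dominantFactor))))
}

#' Compute the composite quality index
#'
#' \deqn{KCQI = \ln(1000 \cdot F \cdot L^* \cdot b^* \cdot C / SSC)}
#' with F the firmness and C the chroma: the index rises with firmness,
#' lightness, yellowness and colour saturation and falls as soluble solids
#' accumulate, so it decreases as fruit ripen. The constant 1000 is a pure
#' offset of ln 1000. a* is carried in the quality tables but never enters
#' the index.
#'
#' @param x a quality table (data.frame with columns `firmness`, `L`, `b`,
#'   `chroma`, `ssc`) or a single named record.
#' @return numeric vector of index values, one per row.
#' @examples
#' computeKCQI(data.frame(firmness = 1, L = 1, b = 1, chroma = 1, ssc = 1000))
#' @export
computeKCQI <- function(x) {
    x <- as.data.frame(as.list(x))[
        , c("firmness", "L", "b", "chroma", "ssc"), drop = FALSE]
    for (f in names(x)) {
        bad <- !is.finite(x[[f]]) | x[[f]] <= 0
        if (any(bad))
            stop(sprintf(
                "field '%s' must be positive for the quality index (row %d)",
                f, which(bad)[1]))
    }
    log(1000 * x$firmness * x$L * x$b * x$chroma / x$ssc)
}

#' @rdname computeKCQI
#' @param table a quality table.
#' @return `addKCQI`: the table with a `kcqi` column appended.
#' @export
addKCQI <- function(table) {
    table$kcqi <- computeKCQI(table)
    table
}
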