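# SIMPLS partial least squares (de Jong 1993) for a single response.
# Returns the coefficient path over 1..ncomp components so that a single fit
# serves model selection. Written here because no PLS package ships with the
# package's dependency set; tests cross-check it against the closed-form
# least-squares solution at full rank and against an independent PLS
# implementation at reduced rank.

simplsFit <- function(X, y, ncomp) {
    X <- as.matrix(X)
    n <- nrow(X); p <- ncol(X)
    ncomp <- min(ncomp, p, n - 1L)
    xm <- colMeans(X); ym <- mean(y)
    X0 <- sweep(X, 2, xm)
    y0 <- y - ym
    S <- crossprod(X0, y0)              # p x 1
    R <- matrix(0, p, ncomp)            # X weights
    Q <- numeric(ncomp)                 # y loadings
    V <- matrix(0, p, ncomp)            # orthogonalised X loadings
    B <- matrix(0, p, ncomp)            # coefficient path
    for (a in seq_len(ncomp)) {
        r <- S
        t <- X0 %*% r
        t <- t - mean(t)
        nt <- sqrt(sum(t^2))
        if (nt < 1e-12) { ncomp <- a - 1L; break }
        t <- t / nt; r <- r / nt
        pp <- crossprod(X0, t)
        qq <- sum(y0 * t)
        v <- pp
        if (a > 1) {
            Vp <- V[, seq_len(a - 1), drop = FALSE]
            v <- v - Vp %*% crossprod(Vp, pp)
        }
        v <- v / sqrt(sum(v^2))
        S <- S - v %*% crossprod(v, S)
        R[, a] <- r; Q[a] <- qq; V[, a] <- v
        B[, a] <- R[, seq_len(a), drop = FALSE] %*% Q[seq_len(a)]
    }
    if (ncomp < 1L) stop("no usable PLS component (constant predictors?)")
    list(coef = B[, seq_len(ncomp), drop = FALSE], xMeans = xm, yMean = ym,
         ncomp = ncomp)
}

# Predict from a simplsFit; `ncomp` selects a point on the coefficient path
# (default: the largest fitted).
simplsPredict <- function(fit, X, ncomp = fit$ncomp) {
    ncomp <- min(ncomp, fit$ncomp)
    drop(sweep(as.matrix(X), 2, fit$xMeans) %*% fit$coef[, ncomp]) + fit$yMean
}

# Deterministic interleaved fold assignment (no RNG): sample i goes to fold
# ((i - 1) mod k) + 1.
interleavedFolds <- function(n, k) rep_len(seq_len(k), n)

# k-fold cross-validated RMSE for every component count 1..maxComp in one
# sweep. `folds` may be an integer (interleaved assignment) or a vector.
plsRMSECV <- function(X, y, maxComp, folds = 5L) {
    n <- nrow(X)
    fold <- if (length(folds) == 1L) interleavedFolds(n, folds) else folds
    maxComp <- min(maxComp, ncol(X), n - max(table(fold)) - 1L)
    if (maxComp < 1L) maxComp <- 1L
    press <- numeric(maxComp)
    for (f in unique(fold)) {
        hold <- fold == f
        fit <- simplsFit(X[!hold, , drop = FALSE], y[!hold], maxComp)
        for (a in seq_len(maxComp)) {
            pr <- simplsPredict(fit, X[hold, , drop = FALSE],
                                min(a, fit$ncomp))
            press[a] <- press[a] + sum((y[hold] - pr)^2)
        }
    }
    sqrt(press / n)
}
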