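smallDs <- local({
    val <- NULL
    function() {
        if (is.null(val)) val <<- makeDataset(seed = 51)
        val
    }
})

test_that("SPXY assigns round(fraction * n) samples to calibration", {
    set.seed(60)
    ds <- spectralDataset(matrix(rnorm(10 * 4), 10, 4), rnorm(10),
                          spectralAxis(wavelengths = 1:4))
    sp <- spxySplit(ds, 0.8)
    expect_equal(length(calibrationIdx(sp)), 8)
    expect_equal(length(predictionIdx(sp)), 2)
    big <- spxySplit(smallDs()$ds, 0.8)
    expect_equal(length(calibrationIdx(big)), 192)
    expect_equal(length(predictionIdx(big)), 48)
})

test_that("SPXY places the response extremes in the calibration set", {
    set.seed(61)
    y <- rnorm(30)
    X <- cbind(y, y)                      # X distance mirrors y distance
    ds <- spxySplit(spectralDataset(X, y, spectralAxis(wavelengths = 1:2)))
    expect_true(which.min(y) %in% calibrationIdx(ds))
    expect_true(which.max(y) %in% calibrationIdx(ds))
})

test_that("SPXY matches a brute-force transcription of the greedy rule", {
    set.seed(62)
    X <- matrix(rnorm(6 * 3), 6, 3)
    y <- rnorm(6)
    ds <- spxySplit(spectralDataset(X, y, spectralAxis(wavelengths = 1:3)),
                    calibrationFraction = 4 / 6)
    # independent re-derivation
    dX <- as.matrix(dist(X)); dY <- abs(outer(y, y, "-"))
    D <- dX / max(dX) + dY / max(dY)
    pick <- sort(which(D == max(D), arr.ind = TRUE)[1, ])
    while (length(pick) < 4) {
        cand <- setdiff(1:6, pick)
        score <- vapply(cand, function(i) min(D[i, pick]), numeric(1))
        pick <- c(pick, cand[which.max(score)])
    }
    expect_setequal(calibrationIdx(ds), pick)
})

test_that("SPXY refuses tiny datasets", {
    ds <- spectralDataset(matrix(rnorm(8), 4, 2), rnorm(4),
                          spectralAxis(wavelengths = 1:2))
    expect_error(spxySplit(ds), "at least 5")
})

test_that("selectors demand a split and never read prediction rows", {
    d <- makeDataset(seed = 52, split = FALSE)
    expect_error(spaSelect(d$ds), "calibration split")
    ds <- spxySplit(d$ds)
    poisoned <- ds
    # destroy the prediction rows; any selector touching them must change
    poisoned@X[predictionIdx(ds), ] <- 1e6
    poisoned@y[predictionIdx(ds)] <- -1e6
    expect_identical(spaSelect(ds)@indices, spaSelect(poisoned)@indices)
    expect_identical(carsSelect(ds, seed = 5)@indices,
                     carsSelect(poisoned, seed = 5)@indices)
    expect_identical(rfrogSelect(ds, nIterations = 150, seed = 5)@indices,
                     rfrogSelect(poisoned, nIterations = 150, seed = 5)@indices)
})

test_that("returned wavelengths map bijectively back to band indices", {
    ds <- smallDs()$ds
    for (b in list(spaSelect(ds), carsSelect(ds, seed = 3),
                   rfrogSelect(ds, nIterations = 150, seed = 3))) {
        expect_false(is.unsorted(b@indices, strictly = TRUE))
        expect_identical(bandNearest(ds@axis, b@wavelengths), b@indices)
    }
})

# -- SPA -------------------------------------------------------------------

test_that("SPA never selects a duplicated column after its twin", {
    set.seed(63)
    X <- matrix(rnorm(40 * 6), 40, 6)
    X <- cbind(X, X[, 3])                 # column 7 duplicates column 3
    y <- rnorm(40)
    ds <- spxySplit(spectralDataset(X, y, spectralAxis(wavelengths = 1:7)))
    b <- spaSelect(ds, maxBands = 6)
    expect_false(all(c(3, 7) %in% b@indices))
})

test_that("SPA recovers an exact sparse model over orthogonal columns", {
    set.seed(65)
    n <- 64
    X <- qr.Q(qr(matrix(rnorm(n * 12), n, 12))) # orthonormal columns
    X[, 1:3] <- X[, 1:3] * 1.01   # deterministic tie-break for the chains
    y <- 2 * X[, 1] - 3 * X[, 2] + X[, 3]
    ds <- spectralDataset(X, y, spectralAxis(wavelengths = 1:12))
    ds@split <- rep("calibration", n)
    b <- spaSelect(ds, maxBands = 8, alpha = 0.25)
    expect_setequal(b@indices, 1:3)
    expect_lt(sqrt(mean(lm(y ~ X[, b@indices])$residuals^2)), 1e-10)
})

test_that("SPA projection chains equal a Gram-Schmidt oracle", {
    set.seed(64)
    n <- 30; p <- 12
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    ds <- spectralDataset(X, y, spectralAxis(wavelengths = 1:p))
    ds@split <- rep("calibration", n)
    # oracle: explicit Gram-Schmidt residualisation from a fixed start
    oracleChain <- function(Xc, start, m) {
        basis <- list(); chain <- start
        v <- Xc[, start]
        for (step in 2:m) {
            basis[[step - 1]] <- v / sqrt(sum(v^2))
            Rres <- Xc
            for (b in basis) Rres <- Rres - b %*% crossprod(b, Rres)
            norms <- colSums(Rres^2); norms[chain] <- -Inf
            nxt <- which.max(norms)
            chain <- c(chain, nxt)
            v <- Rres[, nxt]
        }
        chain
    }
    Xc <- scale(X, center = TRUE, scale = FALSE)
    for (start in c(1, 5, 12)) {
        got <- kcqi:::spaChain(Xc, start, 6)
        expect_identical(got, oracleChain(Xc, start, 6),
                         info = paste("start", start))
    }
})

# -- CARS ------------------------------------------------------------------

test_that("CARS is seed-deterministic with a non-increasing retained path", {
    ds <- smallDs()$ds
    b1 <- suppressWarnings(carsSelect(ds, seed = 9))
    b2 <- suppressWarnings(carsSelect(ds, seed = 9))
    expect_identical(b1@indices, b2@indices)
    expect_true(all(diff(b1@diagnostics$retainedCounts) <= 0))
    expect_equal(b1@diagnostics$bestRun,
                 which.min(b1@diagnostics$rmsecvPath))
})

test_that("CARS recovers a planted sparse signal", {
    pl <- makePlanted(seed = 71)
    hits <- vapply(1:10, function(s) {
        b <- suppressWarnings(carsSelect(pl$ds, seed = s))
        sum(pl$planted %in% b@indices)
    }, numeric(1))
    expect_gte(median(hits), 4)
})

# -- random frog -----------------------------------------------------------

test_that("random frog validates its threshold and reports probabilities", {
    ds <- smallDs()$ds
    expect_error(rfrogSelect(ds, threshold = 0), "strictly inside")
    expect_error(rfrogSelect(ds, threshold = 1.2), "strictly inside")
    b <- rfrogSelect(ds, nIterations = 200, seed = 4)
    pr <- b@diagnostics$probabilities
    expect_true(all(pr >= 0 & pr <= 1))
    expect_length(pr, nBands(ds@axis))
    expect_setequal(b@indices, which(pr >= 0.40))
})

test_that("a threshold above every selection probability yields an empty subset", {
    ds <- smallDs()$ds
    # eta = 1 accepts every proposal: the chain churns and no band can be
    # present in essentially every iteration
    expect_warning(
        b <- rfrogSelect(ds, nIterations = 200, seed = 4, eta = 1,
                         threshold = 0.999),
        "empty subset")
    expect_length(b@indices, 0)
})

test_that("random frog ranks a planted sparse signal on top", {
    pl <- makePlanted(seed = 72)
    hits <- vapply(1:10, function(s) {
        b <- rfrogSelect(pl$ds, nIterations = 400, seed = s)
        pr <- b@diagnostics$probabilities
        top <- order(pr, decreasing = TRUE)[1:5]
        sum(pl$planted %in% top)
    }, numeric(1))
    expect_gte(median(hits), 4)
})

test_that("on planted data every selector beats an equal-sized random subset", {
    wins <- c(spa = 0, cars = 0, rfrog = 0)
    nSeeds <- 20
    for (s in seq_len(nSeeds)) {
        pl <- makePlanted(seed = 200 + s)
        cal <- kcqi:::calBlock(pl$ds)
        cvOf <- function(idx) min(kcqi:::plsRMSECV(cal$X[, idx, drop = FALSE],
                                                   cal$y, 10, 5))
        sets <- list(
            spa = spaSelect(pl$ds, maxBands = 15)@indices,
            cars = suppressWarnings(carsSelect(pl$ds, seed = s))@indices,
            rfrog = suppressWarnings(rfrogSelect(pl$ds, nIterations = 300,
                                                 seed = s))@indices)
        for (m in names(sets)) {
            idx <- sets[[m]]
            if (!length(idx)) next
            set.seed(5000 + s)
            rnd <- sort(sample(ncol(pl$ds@X), length(idx)))
            if (cvOf(idx) < cvOf(rnd)) wins[m] <- wins[m] + 1
        }
    }
    for (m in names(wins)) expect_gte(wins[[m]] / nSeeds, 0.8)
})
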