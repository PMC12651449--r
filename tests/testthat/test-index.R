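randomCorr <- function(p, n = 200, seed) {
    set.seed(seed)
    stats::cor(matrix(rnorm(n * p), n, p) %*% matrix(rnorm(p * p), p, p))
}

test_that("pearsonMatrix recovers exact linear relations and flags constants", {
    x <- seq(-3, 3, length.out = 40)
    M <- cbind(x = x, up = 2 * x + 3, down = -x)
    R <- pearsonMatrix(M)
    expect_equal(R["x", "up"], 1)
    expect_equal(R["x", "down"], -1)
    expect_true(all(diag(R) == 1))
    expect_equal(R, t(R))
    Mc <- cbind(M, flat = rep(5, 40))
    expect_warning(Rc <- pearsonMatrix(Mc), "constant")
    expect_true(all(is.na(Rc["flat", c("x", "up", "down")])))
})

test_that("z-score normalisation is exact and idempotent, and rejects constants", {
    set.seed(21)
    M <- matrix(rnorm(120, 10, 4), 30, 4,
                dimnames = list(NULL, letters[1:4]))
    Z <- zscoreNormalize(M)
    expect_lt(max(abs(colMeans(Z))), 1e-12)
    expect_equal(unname(apply(Z, 2, sd)), rep(1, 4))
    expect_equal(unname(zscoreNormalize(unclass(Z))), unname(Z),
                 tolerance = 1e-12)
    expect_error(zscoreNormalize(cbind(M, k = rep(1, 30))), "constant")
})

test_that("KMO equals 1/2 for any two correlated variables and approaches 1 in the one-factor limit", {
    for (r in c(0.3, -0.8, 0.95))
        expect_equal(kmoMeasure(matrix(c(1, r, r, 1), 2)), 0.5)
    # one common factor, shrinking noise: KMO climbs towards 1
    kmoAt <- function(noise) {
        set.seed(22)
        f <- rnorm(4000)
        M <- sapply(1:6, function(i) f + rnorm(4000, 0, noise))
        kmoMeasure(pearsonMatrix(M))
    }
    ks <- vapply(c(1, 0.5, 0.1, 0.02), kmoAt, numeric(1))
    expect_true(all(diff(ks) > 0))
    expect_gt(ks[4], 0.9)
})

test_that("KMO and Bartlett agree with direct formula evaluation on random matrices", {
    for (s in 1:5) {
        R <- randomCorr(5, seed = s)
        # independent in-test evaluation of the defining formulas
        Ri <- solve(R)
        Q <- -Ri / sqrt(outer(diag(Ri), diag(Ri))); diag(Q) <- 0
        R0 <- R; diag(R0) <- 0
        expect_equal(kmoMeasure(R), sum(R0^2) / (sum(R0^2) + sum(Q^2)),
                     tolerance = 1e-6)
        n <- 123
        b <- bartlettSphericity(R, n)
        expect_equal(unname(b["chi2"]),
                     -(n - 1 - (2 * 5 + 5) / 6) * log(det(R)),
                     tolerance = 1e-6)
        expect_equal(unname(b["df"]), 10)
        expect_equal(unname(b["p"]),
                     pchisq(unname(b["chi2"]), 10, lower.tail = FALSE),
                     tolerance = 1e-9)
    }
})

test_that("Bartlett is null on the identity and explodes towards singularity", {
    b <- bartlettSphericity(diag(4), 50)
    expect_equal(unname(b["chi2"]), 0)
    expect_equal(unname(b["p"]), 1)
    nearSing <- matrix(0.999999, 3, 3); diag(nearSing) <- 1
    expect_gt(bartlettSphericity(nearSing, 50)["chi2"], 1e3)
    sing <- matrix(1, 3, 3)
    expect_equal(unname(bartlettSphericity(sing, 50)["chi2"]), Inf)
})

test_that("factor analysis resolves two uncorrelated blocks exactly", {
    R <- diag(4)
    R[1, 2] <- R[2, 1] <- 1
    R[3, 4] <- R[4, 3] <- 1
    R <- R + diag(1e-9, 4)               # numerically PSD
    fm <- factorAnalysis(R / R[1, 1], varianceThreshold = 80)
    expect_equal(fm@retainedK, 2L)
    L <- abs(fm@loadings)
    blockOf <- apply(L, 1, which.max)
    expect_equal(blockOf[1], blockOf[2])
    expect_equal(blockOf[3], blockOf[4])
    expect_false(blockOf[1] == blockOf[3])
    expect_equal(sort(as.numeric(L)), c(rep(0, 4), rep(1, 4)),
                 tolerance = 1e-4)
})

test_that("varimax rotation conserves communalities", {
    tab <- simulateQualityTable(defaultCfg(), seed = 31)
    fm <- factorAnalysis(tab)
    expect_equal(fm@rotation, "varimax")
    # unrotated loadings from the same eigendecomposition
    e <- eigen(fm@correlation, symmetric = TRUE)
    k <- fm@retainedK
    L0 <- e$vectors[, 1:k] %*% diag(sqrt(e$values[1:k]), k)
    expect_equal(unname(rowSums(fm@loadings^2)), unname(rowSums(L0^2)),
                 tolerance = 1e-8)
})

test_that("factor analysis rejects non-PSD input and NA matrices", {
    bad <- matrix(c(1, 0.9, 0.9, 0.9, 1, -0.9, 0.9, -0.9, 1), 3)
    expect_error(factorAnalysis(bad), "positive semi-definite")
})

test_that("sign convention points each factor's dominant variable positive", {
    tab <- simulateQualityTable(defaultCfg(), seed = 32)
    fm <- factorAnalysis(tab)
    for (j in seq_len(fm@retainedK)) {
        i <- which.max(abs(fm@loadings[, j]))
        expect_gt(fm@loadings[i, j], 0)
    }
})

test_that("the published loading matrix selects the five index parameters", {
    L <- rbind(ssc      = c(-0.807, 0.302, -0.437),
               firmness = c(0.833, -0.408, 0.155),
               L        = c(0.869, 0.277, 0.027),
               a        = c(-0.698, 0.494, 0.504),
               b        = c(0.434, 0.822, -0.048),
               chroma   = c(0.922, 0.331, -0.120))
    sel <- selectParameters(L)
    expect_setequal(sel$selected, c("ssc", "firmness", "L", "b", "chroma"))
    expect_equal(sel$crossLoaded, "a")
    expect_equal(unname(sel$dominantFactor[c("ssc", "firmness", "L",
                                             "chroma")]), rep(1, 4))
    expect_equal(unname(sel$dominantFactor["b"]), 2)
    # the third factor carries no selected variable and is dropped
    expect_setequal(sel$retainedFactors, c(1, 2))
})

test_that("selection degenerates sensibly", {
    weak <- matrix(0.3, 4, 2, dimnames = list(letters[1:4], NULL))
    expect_message(sel <- selectParameters(weak), "empty selection")
    expect_length(sel$selected, 0)
    one <- matrix(c(0.9, 0.1, 0.1, 0.1), 4, 1,
                  dimnames = list(letters[1:4], NULL))
    expect_equal(selectParameters(one)$selected, "a")
})

test_that("the quality index matches its closed form and log arithmetic", {
    expect_equal(computeKCQI(unitRecord()), 0)
    base <- data.frame(firmness = 13.5, L = 55, b = 30, chroma = 31.32,
                       ssc = 12)
    # frozen 40-digit arbitrary-precision evaluation of the index formula
    expect_equal(computeKCQI(base), 17.878325752655749, tolerance = 1e-10)
    doubled <- base; doubled$firmness <- 27
    expect_equal(computeKCQI(doubled) - computeKCQI(base), log(2),
                 tolerance = 1e-12)
    halvedSSC <- base; halvedSSC$ssc <- 6
    expect_equal(computeKCQI(halvedSSC) - computeKCQI(base), log(2),
                 tolerance = 1e-12)
})

test_that("the index is monotone in each of its five inputs", {
    base <- data.frame(firmness = 10, L = 50, b = 25, chroma = 26, ssc = 14)
    up <- function(f, d) { r <- base; r[[f]] <- r[[f]] + d; computeKCQI(r) }
    k0 <- computeKCQI(base)
    for (f in c("firmness", "L", "b", "chroma")) expect_gt(up(f, 1), k0)
    expect_lt(up("ssc", 1), k0)
})

test_that("non-positive inputs are refused with the offending field named", {
    bad <- unitRecord(); bad$L <- 0
    expect_error(computeKCQI(bad), "'L'")
    bad <- unitRecord(); bad$ssc <- -2
    expect_error(computeKCQI(bad), "'ssc'")
})

test_that("mean index declines monotonically across shelf-life days", {
    tab <- addKCQI(simulateQualityTable(defaultCfg(), seed = 35))
    m <- tapply(tab$kcqi, tab$day, mean)
    expect_true(all(diff(m) < 0))
})

test_that("synthetic defaults clear the factor-analysis adequacy gates", {
    tab <- simulateQualityTable(defaultCfg(), seed = 36)
    fm <- factorAnalysis(tab)
    expect_gt(fm@kmo, 0.5)
    expect_lt(fm@bartlett["p"], 1e-10)
    # three factors carry over 90% of the variance
    expect_gt(fm@cumulativeVariance[3], 90)
})
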