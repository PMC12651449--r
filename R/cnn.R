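# One-dimensional convolutional network for spectral regression, written in
# plain matrix algebra. Architecture (fixed):
#   Conv1(kernel 3, same padding) -> BatchNorm -> ReLU ->
#   Conv2(kernel 3, same padding) -> BatchNorm -> ReLU -> Dropout ->
#   FullyConnected -> scalar output,
# trained with Adam on the half-mean-squared-error loss (1/2 * MSE).
# Convolutions are evaluated as im2col matrix products; rows of all
# intermediate matrices are ordered position-fastest within sample.
# Correctness is pinned by a finite-difference gradient check in the tests.

cnnInit <- function(p, channels = c(16L, 32L), kernel = 3L) {
    glorot <- function(fanIn, fanOut, n)
        stats::runif(n, -1, 1) * sqrt(6 / (fanIn + fanOut))
    list(
        p = p, kernel = kernel, channels = channels,
        W1 = matrix(glorot(kernel, channels[1], kernel * channels[1]),
                    kernel, channels[1]),
        b1 = numeric(channels[1]),
        g1 = rep(1, channels[1]), beta1 = numeric(channels[1]),
        rm1 = numeric(channels[1]), rv1 = rep(1, channels[1]),
        W2 = matrix(glorot(kernel * channels[1], channels[2],
                           kernel * channels[1] * channels[2]),
                    kernel * channels[1], channels[2]),
        b2 = numeric(channels[2]),
        g2 = rep(1, channels[2]), beta2 = numeric(channels[2]),
        rm2 = numeric(channels[2]), rv2 = rep(1, channels[2]),
        Wfc = matrix(glorot(p * channels[2], 1, p * channels[2]), p,
                     channels[2]),
        bfc = 0)
}

# Row-gather indices realising a within-sample shift by `o - 1 - pad`
# positions (zero-padded): index 0 marks out-of-range rows.
shiftIndex <- function(p, B, o, pad) {
    t <- seq_len(p)
    src <- t + (o - 1L - pad)
    src[src < 1L | src > p] <- NA_integer_
    idx <- rep(src, B) + rep((seq_len(B) - 1L) * p, each = p)
    idx
}

# im2col for a batch held as a (B*p) x C matrix (position-fastest rows):
# returns (B*p) x (kernel*C) with zero padding, columns ordered channel-major
# ((c-1)*kernel + o) to match the weight layout.
im2col <- function(A, p, B, kernel = 3L) {
    C <- ncol(A)
    pad <- (kernel - 1L) %/% 2L
    blocks <- vector("list", kernel)
    for (o in seq_len(kernel)) {
        idx <- shiftIndex(p, B, o, pad)
        blk <- A[idx, , drop = FALSE]
        blk[is.na(idx), ] <- 0
        blocks[[o]] <- blk
    }
    out <- do.call(cbind, blocks)          # offset-major: [o1 all C | o2 ...]
    # column (o-1)*C + c must land at (c-1)*kernel + o
    target <- integer(kernel * C)
    for (o in seq_len(kernel)) for (c in seq_len(C))
        target[(c - 1L) * kernel + o] <- (o - 1L) * C + c
    out[, target, drop = FALSE]
}

# Adjoint of im2col: scatter gradient columns back onto the input positions.
col2im <- function(G, p, B, C, kernel = 3L) {
    pad <- (kernel - 1L) %/% 2L
    out <- matrix(0, p * B, C)
    for (o in seq_len(kernel)) {
        cols <- (seq_len(C) - 1L) * kernel + o
        blk <- G[, cols, drop = FALSE]
        # adjoint of the forward gather: scatter back along the same index
        idx <- shiftIndex(p, B, o, pad)
        ok <- !is.na(idx)
        out[idx[ok], ] <- out[idx[ok], ] + blk[ok, , drop = FALSE]
    }
    out
}

bnForward <- function(Z, g, beta, rm, rv, training, momentum = 0.9,
                      eps = 1e-5) {
    if (training) {
        mu <- colMeans(Z)
        va <- colMeans(sweep(Z, 2, mu)^2)
        rm <- momentum * rm + (1 - momentum) * mu
        rv <- momentum * rv + (1 - momentum) * va
    } else {
        mu <- rm; va <- rv
    }
    xhat <- sweep(sweep(Z, 2, mu), 2, sqrt(va + eps), "/")
    list(out = sweep(sweep(xhat, 2, g, "*"), 2, beta, "+"),
         xhat = xhat, va = va, rm = rm, rv = rv, eps = eps)
}

bnBackward <- function(dOut, cache, g) {
    xhat <- cache$xhat
    dg <- colSums(dOut * xhat)
    dbeta <- colSums(dOut)
    m <- nrow(dOut)
    dXhat <- sweep(dOut, 2, g, "*")
    dZ <- sweep(dXhat - matrix(colMeans(dXhat), m, ncol(dOut), byrow = TRUE) -
                xhat * matrix(colMeans(dXhat * xhat), m, ncol(dOut),
                              byrow = TRUE),
                2, sqrt(cache$va + cache$eps), "/")
    list(dZ = dZ, dg = dg, dbeta = dbeta)
}

# Forward pass on standardized input X (B x p). In training mode the dropout
# mask and the caches needed by cnnBackward are returned; in eval mode
# dropout is inactive and batch-norm uses its running statistics.
cnnForward <- function(net, X, training = FALSE, dropout = 0.2,
                       dropMask = NULL) {
    B <- nrow(X); p <- net$p
    if (ncol(X) != p) stop("input length ", ncol(X),
                           " does not match the network's ", p, " bands")
    A0 <- matrix(as.vector(t(X)), B * p, 1L)      # position-fastest rows
    C1 <- im2col(A0, p, B, net$kernel)
    Z1 <- sweep(C1 %*% net$W1, 2, net$b1, "+")
    bn1 <- bnForward(Z1, net$g1, net$beta1, net$rm1, net$rv1, training)
    A1 <- pmax(bn1$out, 0)
    C2 <- im2col(A1, p, B, net$kernel)
    Z2 <- sweep(C2 %*% net$W2, 2, net$b2, "+")
    bn2 <- bnForward(Z2, net$g2, net$beta2, net$rm2, net$rv2, training)
    A2 <- pmax(bn2$out, 0)
    if (training && dropout > 0) {
        if (is.null(dropMask))
            dropMask <- matrix(stats::rbinom(length(A2), 1, 1 - dropout),
                               nrow(A2), ncol(A2)) / (1 - dropout)
        A2d <- A2 * dropMask
    } else {
        A2d <- A2
        dropMask <- NULL
    }
    pos <- rep(seq_len(p), B)
    samp <- rep(seq_len(B), each = p)
    pred <- as.numeric(rowsum(rowSums(A2d * net$Wfc[pos, , drop = FALSE]),
                              samp)) + net$bfc
    list(pred = pred, A0 = A0, C1 = C1, bn1 = bn1, A1 = A1, C2 = C2,
         bn2 = bn2, A2 = A2, A2d = A2d, dropMask = dropMask, pos = pos,
         samp = samp, B = B)
}

# Backward pass; returns parameter gradients for the half-MSE loss.
cnnBackward <- function(net, fw, y) {
    B <- fw$B; p <- net$p
    dpred <- (fw$pred - y) / B
    dWfc <- rowsum(fw$A2d * dpred[fw$samp], fw$pos)
    dbfc <- sum(dpred)
    dA2d <- net$Wfc[fw$pos, , drop = FALSE] * dpred[fw$samp]
    dA2 <- if (is.null(fw$dropMask)) dA2d else dA2d * fw$dropMask
    dBn2out <- dA2 * (fw$bn2$out > 0)
    bb2 <- bnBackward(dBn2out, fw$bn2, net$g2)
    dW2 <- crossprod(fw$C2, bb2$dZ)
    db2 <- colSums(bb2$dZ)
    dC2 <- tcrossprod(bb2$dZ, net$W2)
    dA1 <- col2im(dC2, p, B, net$channels[1], net$kernel)
    dBn1out <- dA1 * (fw$bn1$out > 0)
    bb1 <- bnBackward(dBn1out, fw$bn1, net$g1)
    dW1 <- crossprod(fw$C1, bb1$dZ)
    db1 <- colSums(bb1$dZ)
    list(W1 = dW1, b1 = db1, g1 = bb1$dg, beta1 = bb1$dbeta,
         W2 = dW2, b2 = db2, g2 = bb2$dg, beta2 = bb2$dbeta,
         Wfc = dWfc, bfc = dbfc)
}

cnnTrainableParams <- c("W1", "b1", "g1", "beta1", "W2", "b2", "g2", "beta2",
                        "Wfc", "bfc")

adamInit <- function(net) {
    st <- list(t = 0)
    for (nm in cnnTrainableParams) {
        st[[paste0("m.", nm)]] <- net[[nm]] * 0
        st[[paste0("v.", nm)]] <- net[[nm]] * 0
    }
    st
}

adamStep <- function(net, grads, st, lr = 1e-3, b1 = 0.9, b2 = 0.999,
                     eps = 1e-8) {
    st$t <- st$t + 1
    for (nm in cnnTrainableParams) {
        g <- grads[[nm]]
        st[[paste0("m.", nm)]] <- b1 * st[[paste0("m.", nm)]] + (1 - b1) * g
        st[[paste0("v.", nm)]] <- b2 * st[[paste0("v.", nm)]] + (1 - b2) * g^2
        mhat <- st[[paste0("m.", nm)]] / (1 - b1^st$t)
        vhat <- st[[paste0("v.", nm)]] / (1 - b2^st$t)
        net[[nm]] <- net[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
    list(net = net, st = st)
}

#' One-dimensional convolutional network regression
#'
#' Trains the fixed two-convolution architecture (see the package source
#' header in `R/cnn.R`) on standardised calibration spectra with Adam and
#' half-mean-squared-error loss. Inputs are standardised per band and the
#' response centred/scaled using calibration statistics; predictions are
#' mapped back to the original scale. After every epoch the full calibration
#' set is evaluated in eval mode (no dropout, running batch-norm statistics)
#' and the epoch's `rmse` and `loss = rmse^2 / 2` recorded; the parameters
#' of the best epoch are kept.
#'
#' @param ds a split [SpectralDataset-class].
#' @param bands a [BandSubset-class] (default: full spectrum).
#' @param channels feature channels of the two convolution layers.
#' @param kernel convolution kernel width (odd; default 3). Inputs shorter
#'   than the kernel are rejected.
#' @param dropout drop rate after the second activation (default 0.2).
#' @param lr Adam learning rate (default 1e-3).
#' @param epochs training epochs (default 200).
#' @param batch mini-batch size (default 32).
#' @param seed integer seed (initialisation, shuffling, dropout).
#' @return a [FitResult-class] with per-epoch history and calibration
#'   metrics filled.
#' @export
fitCNN1D <- function(ds, bands = fullBands(ds), channels = c(16L, 32L),
                     kernel = 3L, dropout = 0.2, lr = 1e-3, epochs = 200L,
                     batch = 32L, seed = 1L) {
    cal <- calBlock(ds)
    X <- cal$X[, bands@indices, drop = FALSE]
    y <- cal$y
    p <- ncol(X); n <- nrow(X)
    if (p < kernel)
        stop("input length ", p, " is below the network's receptive field (",
             kernel, ")")
    if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
    xc <- colMeans(X)
    xs <- apply(X, 2, stats::sd)
    xs[xs == 0] <- 1
    Z <- sweep(sweep(X, 2, xc), 2, xs, "/")
    yc <- mean(y); ys <- stats::sd(y)
    if (ys == 0) ys <- 1
    yz <- (y - yc) / ys
    withSeed(seed, {
        net <- cnnInit(p, channels, kernel)
        st <- adamInit(net)
        hist <- data.frame(epoch = integer(0), loss = numeric(0),
                           rmse = numeric(0))
        best <- list(loss = Inf, net = net)
        for (e in seq_len(epochs)) {
            ord <- sample.int(n)
            for (b0 in seq(1, n, by = batch)) {
                idx <- ord[b0:min(b0 + batch - 1L, n)]
                fw <- cnnForward(net, Z[idx, , drop = FALSE], training = TRUE,
                                 dropout = dropout)
                gr <- cnnBackward(net, fw, yz[idx])
                # persist the running batch-norm statistics
                net$rm1 <- fw$bn1$rm; net$rv1 <- fw$bn1$rv
                net$rm2 <- fw$bn2$rm; net$rv2 <- fw$bn2$rv
                up <- adamStep(net, gr, st, lr = lr)
                net <- up$net; st <- up$st
            }
            predZ <- cnnForward(net, Z, training = FALSE)$pred
            rmseE <- rmse(y, predZ * ys + yc)
            lossE <- rmseE^2 / 2
            hist <- rbind(hist, data.frame(epoch = e, loss = lossE,
                                           rmse = rmseE))
            if (lossE < best$loss) best <- list(loss = lossE, net = net)
        }
        out <- newFitResult("cnn", best$net, bands@indices,
                            xCenter = xc, xScale = xs, yCenter = yc,
                            yScale = ys, history = hist)
        out@calibration <- evalMetrics(y, predict(out, X))
        out
    })
}
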