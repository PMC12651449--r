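# Internal helpers: seeded execution and derived sub-seeds.

# Run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG afterwards. A NULL seed runs `expr` with the ambient RNG.
withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

# Deterministically derive a sub-seed below 2^31 from a base seed and a tag,
# so every stochastic stage of a pipeline gets its own reproducible stream.
deriveSeed <- function(seed, tag) {
    m <- 2147483629
    h <- 0
    for (k in utf8ToInt(as.character(tag))) h <- (h * 31 + k) %% m
    # multiply in double precision in two halves to stay exact below 2^53
    s <- as.numeric(seed) %% m
    lo <- (s %% 65536) * 69621 %% m
    hi <- (s %/% 65536) * 69621 %% m
    as.integer(((hi * 65536) %% m + lo + h) %% m)
}

# Population (n-denominator) standard deviation.
popSD <- function(x) sqrt(mean((x - mean(x))^2))

rmse <- function(obs, pred) sqrt(mean((obs - pred)^2))
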