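## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
## All user-facing randomness in the package goes through this.
.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, globalenv())
        else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

## sample without the length-1 surprise of base::sample
.sampleFrom <- function(x, k, replace = FALSE) {
    x[sample.int(length(x), k, replace = replace)]
}
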