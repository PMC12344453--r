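#' @include AllClasses.R
NULL

## Run code with a local RNG state: seeds deterministically, restores the
## caller's .Random.seed afterwards.
localSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## clamp to [0, 1] preserving dim attributes (pmin/pmax with a scalar
## first argument would drop them)
clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

## quantile type 7 without names
q7 <- function(x, p) unname(stats::quantile(x, p, type = 7, names = FALSE))

stopifnot2 <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)

## signal or bare numeric -> numeric vector + Fs
asSamples <- function(x) {
  if (methods::is(x, "Signal")) x@samples else as.numeric(x)
}
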