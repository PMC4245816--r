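## A seeded random generator threaded explicitly through all sampling.
## Wraps R's Mersenne-Twister stream in an environment so package sampling
## never perturbs (and is never perturbed by) the caller's global RNG state.

#' @keywords internal
.sedc_rng <- function(seed) {
  e <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  set.seed(as.integer(seed))
  e$state <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  class(e) <- "sedc_rng"
  e
}

#' @keywords internal
.rng_eval <- function(rng, f) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", globalenv())
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  f()
}

#' @keywords internal
.rng_sample <- function(rng, x, size = NULL, replace = FALSE, prob = NULL) {
  .rng_eval(rng, function() {
    if (is.null(size)) sample(x, replace = replace, prob = prob)
    else sample(x, size = size, replace = replace, prob = prob)
  })
}

#' @keywords internal
.rng_int <- function(rng, lo, hi) {
  .rng_eval(rng, function() sample(seq.int(lo, hi), 1L))
}
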