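#' Derive reproducible sub-seeds from a master seed
#'
#' Experiment protocols split a single master seed into independent streams
#' (network construction, pattern draw, training noise, decay noise, probe
#' noise) so that, for example, inserting extra read-only probes never
#' perturbs the plastic simulation stream.  The global RNG state of the
#' caller is saved and restored.
#'
#' @param seed single integer master seed.
#' @param n number of sub-seeds to derive.
#' @return integer vector of `n` seeds in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(n), length(n) == 1L, n >= 1)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, as.integer(n))
}

# run code under a temporary seed, restoring the caller's RNG state;
# seed = NULL leaves the current stream untouched
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  force(code)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
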