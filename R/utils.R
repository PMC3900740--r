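# Run expr with a private RNG stream: the global .Random.seed is saved and
# restored so seeded package functions never disturb the caller's RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Wrap angles in degrees to (-180, 180].
wrap_deg <- function(x) {
  y <- x %% 360
  y[y > 180] <- y[y > 180] - 360
  y
}

# Wrap fractional shifts to (-0.5, 0.5].
wrap_frac <- function(x) {
  y <- x %% 1
  y[y > 0.5] <- y[y > 0.5] - 1
  y
}

`%||%` <- function(a, b) if (is.null(a)) b else a
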