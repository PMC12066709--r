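# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded generators are
#' byte-reproducible without disturbing the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# Combine a user seed with a stream index into a valid 32-bit seed.
combine_seed <- function(seed, index) {
  (abs(as.integer(seed)) %% 1000003L) * 2011L + as.integer(index) %% 2011L
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopifnot_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a single positive finite number", name),
         call. = FALSE)
  invisible(x)
}

# micrometre <-> SI conversions used throughout; lengths are stored in um
# and converted only at physics boundaries (one conversion table):
#   1 um  = 1e-6 m = 1e-4 cm
#   1 um^2 = 1e-12 m^2
#   1 um^3 = 1e-15 L
#   1 umol L^-1 = 1e-3 mol m^-3 = 1e-9 mol cm^-3
#   1 h = 3600 s
UM_PER_M <- 1e6
UM_PER_CM <- 1e4
L_PER_UM3 <- 1e-15
MOLM3_PER_UM <- 1e-3   # mol m^-3 per umol L^-1
S_PER_H <- 3600
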