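## Internal helpers: argument checks, unit conversions, seeded evaluation.

.assertNumber <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single non-missing number", name),
         call. = FALSE)
  if (strict_lower && x <= lower)
    stop(sprintf("'%s' must be > %g (got %g)", name, lower, x), call. = FALSE)
  if (!strict_lower && x < lower)
    stop(sprintf("'%s' must be >= %g (got %g)", name, lower, x), call. = FALSE)
  if (x > upper)
    stop(sprintf("'%s' must be <= %g (got %g)", name, upper, x), call. = FALSE)
  invisible(x)
}

.assertString <- function(x, name) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single character string", name),
         call. = FALSE)
  invisible(x)
}

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
## All stochastic generators in the package funnel through this so that a
## single integer seed reproduces a dataset byte-for-byte.
withSeed <- function(seed, expr) {
  if (length(seed) != 1L || is.na(seed) || !is.numeric(seed) ||
      seed != as.integer(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed)
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (has_seed)
      assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Unit conversions. Internal convention: masses in grams, volumes in litres,
## times in seconds; user-facing flow rates are mL/min (instrument uptake) and
## ionic concentrations ug/L. One conversion boundary, here.
.flowLitrePerSec <- function(settings) settings@flowRate * 1e-3 / 60
.flowLitrePerMin <- function(settings) settings@flowRate * 1e-3
.acqMinutes      <- function(settings) settings@acquisitionTime / 60

## grams <-> femtograms
.gToFg <- function(g) g * 1e15
.fgToG <- function(fg) fg * 1e-15

.sphereMassG <- function(diameter_nm, density_g_cm3, mass_fraction = 1) {
  d_cm <- diameter_nm * 1e-7
  (pi / 6) * d_cm^3 * density_g_cm3 * mass_fraction
}
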