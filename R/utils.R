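#' @keywords internal
#' @importFrom stats rnorm runif rbinom coef var median setNames
#' @importFrom stats pchisq qchisq simulate residuals fitted vcov logLik
#' @importFrom utils head tail
"_PACKAGE"

# internal argument checks ----------------------------------------------

stop_if <- function(cond, ...) {
  if (cond) stop(sprintf(...), call. = FALSE)
}

check_fraction <- function(x, name) {
  stop_if(!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1,
          "`%s` must be a single value in [0, 1], got %s", name,
          paste(format(x), collapse = ", "))
  invisible(x)
}

# Per-stage RNG streams derived from one master seed.  Offsets keep the
# derived seeds well below 2^31 for any small master seed.
derive_seed <- function(seed, stage) {
  offsets <- c(founders = 11L, gene_drop = 23L, phenotypes = 37L,
               records = 53L, harvest = 71L)
  stage_off <- offsets[[stage]]
  (as.integer(seed) %% 1000000L) * 1000L + stage_off
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample() misreads a length-one vector as 1:x; this never does
sample_range <- function(lo, hi, n) {
  vals <- seq.int(lo, hi)
  vals[sample.int(length(vals), n, replace = TRUE)]
}
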