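#' @importFrom stats rnorm runif median coef lm optim sd fft quantile
#' @importFrom utils head tail write.csv read.csv
NULL

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All stochastic operations in the package
# funnel through this so that seeds are explicit and composable.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a parent seed and a stream index, staying below
# 2^31 so the result is a valid R integer seed.
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + as.numeric(stream) * 16807) %% 2147483587L)
}

#' Convert resistivity to conductivity
#'
#' Tissue properties in the lung-imaging literature are usually quoted as
#' resistivities in ohm metres (for example, lung tissue spans roughly
#' 700 to 2500 ohm.m at 100 kHz over the breathing cycle); the package works
#' internally in conductivities (S/m).
#'
#' @param rho_ohm_m resistivity in ohm metres (positive)
#' @return conductivity in siemens per metre
#' @export
resistivity_to_conductivity <- function(rho_ohm_m) {
  stopifnot(all(rho_ohm_m > 0))
  1 / rho_ohm_m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
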