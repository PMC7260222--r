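# Measurement-noise configuration shared by all simulators.

#' Noise configuration for the synthetic-data generators
#'
#' Bundles the stochastic knobs of the simulators. The regime
#' `tmt_kappa = 1`, `lognormal_sigma = 0`, `nb_dispersion = 0` is noise-free:
#' every downstream estimator recovers its planted quantity exactly.
#'
#' @param lognormal_sigma Multiplicative measurement noise on the natural-log
#'   scale (>= 0); each simulated abundance/intensity cell is multiplied by
#'   `exp(rnorm(1, 0, lognormal_sigma))`.
#' @param tmt_kappa Isobaric ratio-compression exponent in (0, 1]. Observed
#'   TMT ratios to the reference are `true_ratio ^ tmt_kappa`; `1` means no
#'   compression.
#' @param nb_dispersion Negative-binomial dispersion (1/size) of simulated
#'   sequencing counts (>= 0); `0` gives exact expected counts.
#' @param library_size Reads per gradient fraction for count simulation
#'   (positive integer-valued).
#' @param seed Integer seed; generators are pure functions of
#'   (configuration, seed).
#' @return An object of class `noise_config`.
#' @export
noise_config <- function(lognormal_sigma = 0, tmt_kappa = 1,
                         nb_dispersion = 0, library_size = 1e6,
                         seed = 1L) {
  if (!is.numeric(lognormal_sigma) || length(lognormal_sigma) != 1 ||
      is.na(lognormal_sigma) || lognormal_sigma < 0) {
    stop("`lognormal_sigma` must be a single number >= 0")
  }
  if (!is.numeric(tmt_kappa) || length(tmt_kappa) != 1 || is.na(tmt_kappa) ||
      tmt_kappa <= 0 || tmt_kappa > 1) {
    stop("`tmt_kappa` must be a single number in (0, 1]")
  }
  if (!is.numeric(nb_dispersion) || length(nb_dispersion) != 1 ||
      is.na(nb_dispersion) || nb_dispersion < 0) {
    stop("`nb_dispersion` must be a single number >= 0")
  }
  if (!is.numeric(library_size) || length(library_size) != 1 ||
      is.na(library_size) || library_size <= 0) {
    stop("`library_size` must be a single positive number")
  }
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("`seed` must be a single integer")
  }
  structure(
    list(lognormal_sigma = as.numeric(lognormal_sigma),
         tmt_kappa = as.numeric(tmt_kappa),
         nb_dispersion = as.numeric(nb_dispersion),
         library_size = as.numeric(library_size),
         seed = as.integer(seed)),
    class = "noise_config"
  )
}

#' @export
print.noise_config <- function(x, ...) {
  cat("<noise_config> sigma=", x$lognormal_sigma, " kappa=", x$tmt_kappa,
      " nb_dispersion=", x$nb_dispersion, " library_size=", x$library_size,
      " seed=", x$seed, "\n", sep = "")
  invisible(x)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. `offset` decorrelates the streams of the different simulators that
# share one user-facing seed.
with_seed <- function(seed, expr, offset = 0L) {
  seed <- (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
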