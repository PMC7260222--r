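# Simulators for the protein-side experiments: pulse-SILAC label splitting
# and fraction-level protein abundance tables.

#' Heavy-label fraction after a SILAC pulse
#'
#' First-order turnover model of metabolic pulse labeling: after a pulse of
#' `pulse_hours` in heavy (R10K8) medium, the fraction of a protein's pool
#' that is heavy-labeled is `1 - 2^(-t / halflife)`. The share is 0 at t = 0,
#' strictly increasing in t, and approaches (never reaches) 1.
#'
#' @param truth A `truth_table` (uses its `turnover_halflife` column), or a
#'   numeric vector of half-lives in hours.
#' @param pulse_hours Pulse duration in hours (>= 0).
#' @return Numeric vector of heavy fractions in `[0, 1)`, named by entity
#'   where available.
#' @export
simulate_psilac_split <- function(truth, pulse_hours) {
  if (!is.numeric(pulse_hours) || length(pulse_hours) != 1 ||
      is.na(pulse_hours) || pulse_hours < 0) {
    stop("`pulse_hours` must be a single number >= 0")
  }
  if (inherits(truth, "truth_table")) {
    half <- truth$turnover_halflife
    nm <- truth$entity_id
  } else {
    half <- as.numeric(truth)
    nm <- names(truth)
  }
  if (any(!is.finite(half)) || any(half <= 0)) {
    stop("turnover half-lives must be positive and finite")
  }
  stats::setNames(1 - 2^(-pulse_hours / half), nm)
}

#' Simulate a fraction-level protein abundance table
#'
#' For each entity and condition, the planted base abundance is partitioned
#' across the free/monosome/polysome compartments by the planted engagement
#' weights, spread uniformly over the member fractions of each compartment
#' (fractions are equal-volume), split into light/heavy SILAC channels by the
#' pulse-label share, and finally multiplied by per-cell lognormal measurement
#' noise. Before noise, per-entity compartment masses sum to the base
#' abundance in every condition.
#'
#' At `lognormal_sigma = 0` the polysome/free abundance ratio recomputed from
#' the table equals the planted `w_poly / w_free` exactly.
#'
#' @param truth A `truth_table`.
#' @param scheme A `fraction_scheme`.
#' @param noise A `noise_config` (uses `lognormal_sigma` and `seed`).
#' @param pulse_hours Heavy pulse duration (hours); the MATRIX protocol uses
#'   a 4 h pulse.
#' @param conditions Conditions to emit (default both).
#' @return A data frame of class `protein_fraction_table` with columns
#'   `protein_id, fraction_id, condition, channel, abundance`.
#' @export
simulate_protein_fractions <- function(truth, scheme = default_fraction_scheme(),
                                       noise = noise_config(),
                                       pulse_hours = 4,
                                       conditions = c("normoxia", "hypoxia")) {
  stopifnot(inherits(truth, "truth_table"), inherits(scheme, "fraction_scheme"),
            inherits(noise, "noise_config"))
  heavy <- simulate_psilac_split(truth, pulse_hours)
  comp_of <- scheme$compartment[scheme$fraction_ids]
  n_comp <- table(factor(comp_of, levels = .COMPARTMENTS))

  blocks <- list()
  for (cond in conditions) {
    w <- as.matrix(truth[, paste0(c("w_free_", "w_mono_", "w_poly_"), cond)])
    colnames(w) <- .COMPARTMENTS
    # per-fraction mass: entity x fraction
    per_frac <- vapply(scheme$fraction_ids, function(f) {
      cmp <- comp_of[[f]]
      truth$base_abundance * w[, cmp] / n_comp[[cmp]]
    }, numeric(nrow(truth)))
    for (ch in c("light", "heavy")) {
      share <- if (ch == "heavy") heavy else 1 - heavy
      blocks[[paste(cond, ch)]] <- data.frame(
        protein_id = rep(truth$entity_id, times = length(scheme$fraction_ids)),
        fraction_id = rep(scheme$fraction_ids, each = nrow(truth)),
        condition = cond,
        channel = ch,
        abundance = as.vector(per_frac * share),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  if (noise$lognormal_sigma > 0) {
    out$abundance <- with_seed(noise$seed, offset = 101L, {
      out$abundance * exp(stats::rnorm(nrow(out), 0, noise$lognormal_sigma))
    })
  }
  class(out) <- c("protein_fraction_table", "data.frame")
  out
}
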