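# Simulator for multiplexed TMT pulse-SILAC protein-output experiments.

#' Sample layout for a TMT pulse-SILAC run
#'
#' One pooled sample per (condition, perturbation) cell: a non-silencing (NS)
#' control plus one siRNA knockdown per RBP, under each condition. This mirrors
#' a design in which biological replicates are pooled into a single labeled
#' channel per perturbation.
#'
#' @param rbps Character vector of RBP names (may be empty).
#' @param conditions Conditions to include.
#' @return Data frame with columns `sample_id, condition, perturbation`.
#' @export
tmt_design <- function(rbps, conditions = c("normoxia", "hypoxia")) {
  pert <- c("NS", rbps)
  out <- expand.grid(perturbation = pert, condition = conditions,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$sample_id <- paste(out$condition,
                         ifelse(out$perturbation == "NS", "NS",
                                paste0("si", out$perturbation)), sep = "_")
  out[, c("sample_id", "condition", "perturbation")]
}

#' Simulate TMT channel intensities with ratio compression
#'
#' Each entity's true newly-synthesized output in a sample is its base
#' abundance scaled by the heavy-label share of the pulse, by the planted
#' hypoxia/normoxia output ratio (hypoxic samples), and by the planted
#' silencing effect (knockdown samples). Isobaric ratio compression is modeled
#' as a power law: the observed ratio of a channel to the entity's reference
#' (normoxic NS) output is the true ratio raised to `tmt_kappa`, followed by
#' multiplicative lognormal noise. At `tmt_kappa = 1` and
#' `lognormal_sigma = 0` the true per-sample output ratios are recovered
#' exactly by [relative_output()].
#'
#' @param truth A `truth_table`.
#' @param design Sample layout as from [tmt_design()]; default is the layout
#'   for the truth table's RBPs. Must contain at least one NS sample in every
#'   condition present.
#' @param noise A `noise_config` (uses `tmt_kappa`, `lognormal_sigma`, `seed`).
#' @param pulse_hours Heavy pulse duration; the TMT protocol uses 16 h.
#' @return A data frame of class `tmt_experiment` with columns
#'   `protein_id, sample_id, condition, perturbation, intensity`.
#' @export
simulate_tmt <- function(truth, design = NULL, noise = noise_config(),
                         pulse_hours = 16) {
  stopifnot(inherits(truth, "truth_table"), inherits(noise, "noise_config"))
  if (is.null(design)) design <- tmt_design(attr(truth, "rbps"))
  need <- c("sample_id", "condition", "perturbation")
  if (!all(need %in% names(design))) {
    stop("`design` needs columns ", paste(need, collapse = ", "))
  }
  for (cond in unique(design$condition)) {
    n_cond <- sum(design$condition == cond)
    if (n_cond == 0) stop("condition ", cond, " has zero samples")
    if (!any(design$perturbation[design$condition == cond] == "NS")) {
      stop("condition ", cond, " has no NS sample")
    }
  }
  rbp_perts <- setdiff(unique(design$perturbation), "NS")
  if (length(rbp_perts)) {
    missing_eff <- rbp_perts[!paste0("effect_", rbp_perts) %in% names(truth)]
    if (length(missing_eff)) {
      stop("truth table has no planted effects for: ",
           paste(missing_eff, collapse = ", "))
    }
  }

  heavy <- simulate_psilac_split(truth, pulse_hours)
  ref <- truth$base_abundance * heavy  # normoxic NS output
  blocks <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    cond <- design$condition[i]
    pert <- design$perturbation[i]
    true_int <- ref
    if (cond == "hypoxia") true_int <- true_int * truth$output_ratio
    if (pert != "NS") true_int <- true_int * truth[[paste0("effect_", pert)]]
    obs <- ref * (true_int / ref)^noise$tmt_kappa
    blocks[[i]] <- data.frame(
      protein_id = truth$entity_id,
      sample_id = design$sample_id[i],
      condition = cond,
      perturbation = pert,
      intensity = obs,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  if (noise$lognormal_sigma > 0) {
    out$intensity <- with_seed(noise$seed, offset = 202L, {
      out$intensity * exp(stats::rnorm(nrow(out), 0, noise$lognormal_sigma))
    })
  }
  class(out) <- c("tmt_experiment", "data.frame")
  out
}
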