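# Shared in-code fixtures for the test suite.

# Minimal 4-fraction scheme: 1 free, 1 monosome, 2 polysome (counts 2 and 5).
tiny_scheme <- function() {
  fraction_scheme(c("F", "M", "P2", "P5"),
                  c("free", "monosome", "polysome", "polysome"),
                  c(NA, NA, 2L, 5L))
}

# Hand-built protein fraction table on tiny_scheme(): one condition, light
# channel, given per-compartment sums (polysome split over its 2 fractions).
tiny_protein_table <- function(free, mono, poly, protein = "P1",
                               condition = "normoxia", channel = "light") {
  data.frame(
    protein_id = protein,
    fraction_id = c("F", "M", "P2", "P5"),
    condition = condition,
    channel = channel,
    abundance = c(free, mono, poly / 2, poly / 2),
    stringsAsFactors = FALSE
  )
}

# TMT experiment with one protein per row pattern: intensities by sample.
tiny_tmt <- function(intensities, condition = "hypoxia",
                     perturbations = NULL, protein = "P1") {
  n <- length(intensities)
  if (is.null(perturbations)) perturbations <- c("NS", paste0("R", seq_len(n - 1)))
  data.frame(
    protein_id = protein,
    sample_id = paste0(condition, "_", seq_len(n)),
    condition = condition,
    perturbation = perturbations,
    intensity = intensities,
    stringsAsFactors = FALSE
  )
}
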