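---
title: "Quantifying translatome remodeling from ribosome density fractions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying translatome remodeling from ribosome density fractions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribofrac)
```

## The measurement problem

Cells remodel their translatome — which mRNAs are actively translated, and
how intensely — in response to stresses such as hypoxia, often without
corresponding changes in mRNA abundance. Ribosome density fractionation on a
sucrose gradient separates cytoplasmic material into three functional
compartments: **free** fractions (no ribosome engagement, translationally
inactive), **monosome** fractions (the 40S/60S/80S region, initiation-proximal
signal), and **polysome** fractions (multi-ribosome mRNAs under intense
translation). Three kinds of quantitative readout are layered on this
separation:

1. **Translational engagement of proteins** (RNA-binding proteins and other
   translation machinery): the distribution of a protein's abundance across
   compartments. The primary readout is the **polysome/free** abundance ratio;
   **polysome/monosome** is the secondary readout (monosomes can also carry
   decay-pathway factors), and **monosome/free** serves as an initiation
   proxy. Heavy pulse-SILAC signal is excluded first so the readout reflects
   pre-existing machinery, not protein made during the pulse.

2. **Protein output** under many perturbations at once: pulse-SILAC labels
   newly synthesized protein, TMT multiplexing compares its amount across
   silencing conditions. Relative output is each sample's intensity over the
   within-condition mean. A ±15% multiplicative threshold defines
   oxygen-response classes (Class I: ≥15% decrease under hypoxia, Class III:
   ≥15% increase, Class II: neither) and RBP dependency calls
   (`dependent_down` when silencing an RBP lowers a protein's relative
   output to ≤0.85).

3. **Translation efficiency (TE) of transcripts**: per-gene FPKM from
   sequencing each gradient fraction. TE = polysomal FPKM over free+monosomal
   FPKM; steady-state RNA = the FPKM sum over all fractions. Knockdown/control
   ratios ΔTE and ΔRNA, with an inclusive two-fold rule, place each gene into
   a regulatory quadrant (`te_only`, `rna_only`, `both`, `neither`).

Set-level reports (union coverage of a protein universe by RBP target
portfolios, exclusive UpSet-style intersections, annotation overlap) summarize
how dependency portfolios tile a population such as the hypoxia-inducible
class.

## The synthetic world

Every estimator is verifiable against `generate_truth()`, which plants:

* **Class structure** — proportions default to (0.2, 0.5, 0.3): roughly 30%
  of the population hypoxia-induced, consistent with reported hypoxic
  translatome remodeling. Counts follow deterministic largest-remainder
  rounding, so requested proportions are met exactly and tests need no
  stochastic tolerance. Planted hypoxia/normoxia output ratios are drawn
  uniformly within each class's band — Class I on [0.45, 0.85], Class II on
  [0.86, 1.14], Class III on [1.15, 2.20] — so boundaries are respected by
  construction and a band of near-threshold effects exists for the
  compression contract below.
* **Engagement** — normoxic compartment weights are Dirichlet(2, 2, 3)
  (polysome-tilted, realistic for translation machinery); hypoxia shifts each
  entity's polysome/free ratio by a class-dependent fold (0.8 / 1 / 1.25),
  holding the monosome weight and total mass fixed. Spike-in "activated"
  entities for ranking tests get a fold of 4.
* **Ribosome load** — per-transcript ribosome counts are Poisson(λ) with the
  tail lumped at the gradient's maximum annotated count; λ is Uniform(0.5, 5)
  under normoxia and solved (by monotone root-finding on the expected-TE
  curve) so the hypoxic TE shift matches the planted output ratio, and
  likewise for planted knockdown ΔTE effects.
* **Portfolios** — five RBPs of 80 targets each, threefold-enriched for
  Class III entities, with exact pairwise intersections (10 between
  consecutive pairs). Shared members are drawn per pair from the unused pool,
  then portfolios are filled with exclusive members: every requested
  |A ∩ B| is exact and no entity sits in more than two portfolios.
  Silencing effects default to 0.7× output and 0.25× TE for targets.
* **Turnover and lengths** — half-lives are lognormal around 30 h (so a 16 h
  pulse labels ~30% of a typical pool, a 4 h pulse much less); transcript
  lengths lognormal around 2.5 kb.

The emulated wet-lab protocol pools biological replicates into one
measurement per condition/perturbation, and the generator does the same by
default; designs with replicate channels can be passed explicitly to
`simulate_tmt()`.

Noise has four knobs (`noise_config()`): multiplicative lognormal measurement
noise (σ, natural-log scale) on protein/TMT cells; TMT **ratio compression**
as a power law — observed ratio-to-reference equals the true ratio raised to
κ ∈ (0, 1]; negative-binomial dispersion on sequencing counts; and reads per
fraction. κ = 1, σ = 0, dispersion = 0 is the noise-free regime, in which
every planted quantity is recovered *exactly* — the acceptance suite asserts
this end to end at n = 1000.

**What the generator does not emulate:** peptide-level identification and
rollup, missing values, inter-run batch effects, protein degradation during
the pulse, fraction-to-fraction carryover, or isoform structure. A green test
therefore establishes estimator correctness on the stated generative model,
not robustness to all failure modes of real MS/RNA-seq data.

## Numerical and design choices

* **Inclusive thresholds.** "At least 15%" and "two-fold difference" are read
  inclusively: ratios of exactly 0.85/1.15 and 0.5/2.0 are significant.
  Thresholds are multiplicative and applied after any normalization.
* **Within-condition mean includes the queried sample** (the literal reading
  of relative output against "the average of all samples in a given
  condition"); `include_self = FALSE` gives the leave-one-out variant. A
  consequence worth knowing: with *k* samples in a condition, a planted
  effect *e* on a single target is observed as `e / ((k - 1 + e) / k)`, so an
  0.8 effect crosses the 0.85 boundary only when the condition has enough
  channels (k ≥ 4). The default synthetic design (NS + 5 RBPs) has 6.
* **No pseudocount by default.** Zero denominators flag a ratio undefined
  rather than imputing; ranking and delta classification exclude such
  entries into explicit reports (`excluded`, `unclassifiable` attributes),
  so exclusions are auditable. Proteins detected in only one condition are
  likewise excluded from activation ranking and reported, since no principled
  rank exists for them.
* **Compartment aggregation is a sum** over member fractions (equal-volume
  fractions); a mean option exists and changes no ratio when compartments are
  complete. "Aggregate FPKM" for steady-state RNA is likewise a sum.
* **TE denominator** combines free and monosome sums ("free/monosome" read as
  the union); `denominator = "free"` is available.
* **Minimum-expression filter** (NS steady-state ≥ 1 FPKM) before delta
  classification, to avoid ratio instability at near-zero denominators; the
  filtered genes are reported, and the filter can be disabled.
* **ΔTE and ΔRNA are thresholded independently**, which is what makes the
  quadrant identity (te_only + both = TE-affected marginal) hold by
  construction.
* **Activation score** is the log2 ratio-of-ratios of the primary readout —
  the minimal monotone combination of the two per-condition readouts — with
  deterministic tie-breaking (secondary score, then identifier).
* **Chi-square composition test** uses expected counts from background
  proportions with df = (nonzero background classes − 1); zero-background
  classes are dropped and reported. Raw p-values match the reporting style of
  per-RBP tests; Benjamini–Hochberg adjusted values are added alongside,
  clearly labeled.
* **Sequencing depth models.** The FPKM definition divides by mapped reads
  *in that fraction*. With equal per-fraction depth (`depth_model = "equal"`,
  the default) this introduces a real compositional bias: changing one gene
  set's polysome occupancy rescales every other gene's per-fraction FPKM, so
  noise-free ΔTE recovery is approximate (the planted 0.25 is typically
  estimated ~0.22 at desk scale, within the accepted [0.20, 0.31] band).
  `depth_model = "mass"` sequences each fraction proportionally to its mass
  with a per-run normalizer, making FPKM proportional to transcript mass and
  planted TE ratios exactly recoverable; the test suite uses it to verify
  estimator correctness separately from normalization bias.
* **Compression contract.** Under κ < 1 an observed ratio is r^κ, so a
  planted effect is missed iff r lies in
  (0.85^(1/κ), 1.15^(1/κ)) outside (0.85, 1.15). `compression_miss()`
  computes this set analytically and the suite verifies the classifier
  misses exactly it, for κ ∈ {0.5, 0.75, 1}.
* **Heavy-polysome boundary.** Gradients are annotated with ribosome counts
  2..8 on the default 7 polysome fractions; the ≥5-ribosome mark used by
  `polysome_auc()` is a package convention (the underlying protocol does not
  fix which fraction carries 5 ribosomes), so the boundary is always an
  explicit argument.
* **Seeds.** All generators are pure functions of (configuration, seed); the
  RNG state of the caller is saved and restored, and each simulator offsets
  the seed so the streams of different stages are decorrelated but jointly
  reproducible.

## Known limitations

* The TMT compression law (power law), heavy-label kinetics (half-life form),
  and ribosome-load model (truncated Poisson) are deliberately minimal,
  monotone stand-ins for unspecified instrument physics; each is a config
  knob, not a claim about mechanism.
* Oxygen classification uses NS samples only; with one pooled sample per
  condition a single aberrant channel cannot be detected.
* `exclusive_intersections()` enumerates 2^k patterns and refuses k > 10.
* FPKM tables are consumed, not produced: alignment, quantification, and
  library QC are out of scope.
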