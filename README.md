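# ribofrac

Quantitative analytics for **translatome remodeling** measured by ribosome
density fractionation — for labs that separate cytoplasm on sucrose gradients
into free / monosome / polysome compartments and then ask, protein by protein
and transcript by transcript, who is actually translating.

The package implements three readout layers plus set-level reporting, and a
seeded synthetic-data generator with planted ground truth so every estimator
is testable end to end:

* **Translational engagement of proteins** (MATRIX-style): after excluding
  heavy pulse-SILAC signal, per-protein compartment ratios
  `pf = Σ polysome / Σ free` (primary), `pm = Σ polysome / Σ monosome`
  (secondary), `mf = Σ monosome / Σ free` (initiation proxy), and an
  activation ranking by `log2(pf_hypoxia / pf_normoxia)`.
* **Protein output** (TMT pulse-SILAC): relative output = intensity over the
  within-condition mean; oxygen-response classes at an inclusive ±15%
  threshold (Class I `r ≤ 0.85`, Class II, Class III `r ≥ 1.15` for
  `r = output_hypoxia / output_normoxia`); RBP dependency calls
  (`dependent_down` at `≤ 0.85`); per-RBP chi-square tests of class
  composition against the background, `X² = Σ (O − E)² / E` with expected
  counts from background proportions.
* **Transcript-level regulation** (fraction RNA-seq):
  `TE = Σ polysome FPKM / (Σ free + Σ monosome FPKM)`, steady-state RNA =
  total FPKM; knockdown deltas `ΔTE = TE_kd / TE_NS`, `ΔRNA` likewise;
  inclusive two-fold rule and regulatory quadrants
  (`te_only` / `rna_only` / `both` / `neither`); polysome area-under-curve of
  a gradient trace beyond the ≥5-ribosome mark; comparative Ct
  (`2^−ΔΔCt`) helper.
* **Coverage reports**: union coverage of a universe (e.g., the
  hypoxia-inducible class) by RBP target portfolios, exclusive UpSet-style
  intersection counts, annotation overlap (e.g., documented HIF targets).

## Worked example

```r
library(ribofrac)

# A planted world: 1000 entities, ~30% hypoxia-induced, five RBP portfolios
truth <- generate_truth(1000, seed = 42)
#> <truth_table> 1000 entities; classes: I=200 II=500 III=300; RBPs: HuR, PCBP1, PCBP2, hnRNPA2B1, PTBP1

# --- engagement layer -----------------------------------------------------
scheme <- default_fraction_scheme()          # 2 free / 3 monosome / 7 polysome
light <- filter_silac(simulate_protein_fractions(
  truth, scheme, noise_config(lognormal_sigma = 0.05, seed = 42)))
ranking <- activation_ranking(engagement_ratios(light, scheme, "normoxia"),
                              engagement_ratios(light, scheme, "hypoxia"))
head(ranking, 3)
#>   protein_id primary_score secondary_score rank
#> 1   ENT00830     0.5589520      0.27524327    1
#> 2   ENT00142     0.5303608      0.09048065    2
#> 3   ENT00785     0.5121341      0.28822213    3

# --- protein output layer -------------------------------------------------
tmt <- simulate_tmt(truth, noise = noise_config(tmt_kappa = 0.9, seed = 42))
fit <- classify_translatome(tmt)
fit
#> <translatome_result> 1000 proteins classified: I=193 II=510 III=297
#>   dependent_down targets (threshold 0.15, hypoxia): hnRNPA2B1=80 HuR=80 PCBP1=80 PCBP2=80 PTBP1=80

class3 <- fit$classes$protein_id[fit$classes$oxygen_class == "III"]
union_coverage(class3, fit$portfolios)
#> <coverage_report> union 179/297 = 60.3%
#>   hnRNPA2B1       35 (11.8%)
#>   HuR             47 (15.8%)
#>   PCBP1           48 (16.2%)
#>   PCBP2           41 (13.8%)
#>   PTBP1           33 (11.1%)

# --- transcript layer -----------------------------------------------------
sim <- simulate_fraction_counts(truth, scheme,
  noise_config(nb_dispersion = 0.05, library_size = 1e6, seed = 42))
deltas <- delta_table(te_table(sim$fpkm, scheme), "NS", "siHuR")
quadrant_summary(deltas)$counts
#>  te_only rna_only     both  neither
#>       82        0        0      918
summarize_magnitudes(deltas[deltas$gene_id %in% truth_portfolios(truth)$HuR, ])
#>     axis percent_decrease_geometric percent_decrease_arithmetic median_ratio  n
#> te    te                  80.073862                   79.286044    0.1918541 80
#> rna  rna                   6.086166                    3.782646    0.9743606 80
```

Reading the numbers: mild ratio compression (κ = 0.9) pulls a handful of
near-threshold planted effects across the ±15% boundaries (193/510/297
observed vs 200/500/300 planted — exactly the analytically predicted misses);
the five portfolios cover 60% of the observed hypoxia-induced class; HuR
silencing moves its 80 planted targets at the TE level only (planted
ΔTE = 0.25, estimated median 0.19 under per-fraction FPKM normalization and
NB counting noise), with a ~80% geometric TE decrease versus ~6% at the RNA
level.

## Command line

```sh
Rscript inst/cli/ribofrac.R simulate --config config.yml --seed 1 --outdir out/
Rscript inst/cli/ribofrac.R engagement --input out/proteins_fractions.tsv \
    --scheme out/fraction_scheme.txt --top 20
Rscript inst/cli/ribofrac.R translatome --input out/tmt_intensities.tsv
Rscript inst/cli/ribofrac.R te --input out/fraction_fpkm.tsv \
    --scheme out/fraction_scheme.txt --ns-sample NS --kd-sample siHuR
Rscript inst/cli/ribofrac.R coverage --universe class3.txt --sets hur.txt,pcbp1.txt
```

## Package layout

`R/` — fraction schemes, synthetic generators (`generate_truth`,
`simulate_protein_fractions`, `simulate_psilac_split`, `simulate_tmt`,
`simulate_fraction_counts`, `emit_dataset`), engagement readouts, translatome
classifier, TE/RNomics, coverage reports, CLI. `vignettes/` — methods notes:
models, assumptions, numerical choices, limitations.
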