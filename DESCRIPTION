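Package: ribofrac
Title: Ribosome Density Fractionation Analytics for Translatome Remodeling
Version: 0.1.0
Authors@R:
    person("Polysome", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of translatome remodeling from ribosome
    density fractionation experiments. Computes per-protein translational
    engagement readouts (polysome/free, polysome/monosome, monosome/free)
    from fraction-level protein abundance tables, classifies oxygen-response
    protein output from TMT pulse-SILAC intensities (Class I/II/III at a
    15 percent threshold, RBP dependency calls, chi-square composition
    tests), quantifies translation efficiency versus steady-state RNA
    regulation from fraction-level FPKM tables (delta-TE / delta-RNA
    regulatory quadrants, polysome area-under-curve, comparative Ct), and
    reports RBP target-set coverage (union coverage, exclusive
    intersections, annotation overlap). A seeded synthetic-data generator
    emulates the fractionation, pulse-SILAC, TMT, and fraction RNA-seq
    experiments with planted ground truth so every stage is verifiable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
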