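# Generator module: planted truth, protein fractions, pSILAC split, TMT,
# fraction counts, dataset emission.

test_that("class counts follow largest-remainder rounding exactly", {
  expect_identical(unname(largest_remainder(1000, c(0.2, 0.5, 0.3))),
                   c(200L, 500L, 300L))
  # remainders 0.1/0.2/0.7 at n=10 over (0.21, 0.32, 0.47): floor 2/3/4 + 1
  expect_identical(unname(largest_remainder(10, c(0.21, 0.32, 0.47))),
                   c(2L, 3L, 5L))
  truth <- generate_truth(1000, c(0.2, 0.5, 0.3), rbp_cfg = NULL, seed = 3)
  expect_identical(as.vector(table(truth$class_label)), c(200L, 500L, 300L))
  degen <- generate_truth(10, c(0, 1, 0), rbp_cfg = NULL, seed = 99)
  expect_true(all(degen$class_label == "II"))
})

test_that("planted output ratios respect the class boundaries", {
  truth <- generate_truth(600, rbp_cfg = NULL, seed = 11)
  r <- truth$output_ratio
  cl <- truth$class_label
  expect_true(all(r[cl == "III"] >= 1.15))
  expect_true(all(r[cl == "I"] <= 0.85))
  expect_true(all(r[cl == "II"] > 0.85 & r[cl == "II"] < 1.15))
})

test_that("engagement weights are a partition and loads are valid", {
  truth <- generate_truth(200, rbp_cfg = NULL, seed = 5)
  for (cond in c("normoxia", "hypoxia")) {
    w <- truth[, paste0(c("w_free_", "w_mono_", "w_poly_"), cond)]
    expect_true(all(abs(rowSums(w) - 1) < 1e-9))
    expect_true(all(w >= 0 & w <= 1))
    expect_true(all(truth[[paste0("lambda_", cond)]] >= 0))
  }
  expect_true(all(truth$turnover_halflife > 0))
})

test_that("identical seed and config reproduce the truth table exactly", {
  a <- generate_truth(400, seed = 42, rbp_cfg = default_rbp_config())
  b <- generate_truth(400, seed = 42, rbp_cfg = default_rbp_config())
  expect_identical(a, b)
  c <- generate_truth(400, seed = 43, rbp_cfg = default_rbp_config())
  expect_false(identical(a$output_ratio, c$output_ratio))
})

test_that("portfolios honor sizes and exact pairwise overlaps", {
  cfg <- rbp_config(portfolios = c(A = 50, B = 50),
                    overlaps = data.frame(a = "A", b = "B", size = 10))
  truth <- generate_truth(1000, rbp_cfg = cfg, seed = 21)
  pf <- truth_portfolios(truth)
  expect_length(pf$A, 50)
  expect_length(pf$B, 50)
  expect_length(intersect(pf$A, pf$B), 10)

  # several pairs at once, all exact, still pairwise-disjoint shares
  cfg3 <- rbp_config(portfolios = c(A = 40, B = 40, C = 40),
                     overlaps = data.frame(a = c("A", "B"), b = c("B", "C"),
                                           size = c(7, 5)))
  pf3 <- truth_portfolios(generate_truth(800, rbp_cfg = cfg3, seed = 8))
  expect_length(intersect(pf3$A, pf3$B), 7)
  expect_length(intersect(pf3$B, pf3$C), 5)
  expect_length(Reduce(intersect, pf3), 0)
})

test_that("infeasible overlap specifications name the offending pair", {
  cfg <- rbp_config(portfolios = c(A = 5, B = 50),
                    overlaps = data.frame(a = "A", b = "B", size = 10))
  expect_error(generate_truth(100, rbp_cfg = cfg, seed = 1),
               "\\(A, B\\)")
  cfg2 <- rbp_config(portfolios = c(A = 10, B = 50, C = 50),
                     overlaps = data.frame(a = c("A", "A"), b = c("B", "C"),
                                           size = c(6, 6)))
  expect_error(generate_truth(100, rbp_cfg = cfg2, seed = 1), "portfolio A")
  expect_error(generate_truth(10, rbp_cfg = default_rbp_config(), seed = 1),
               "exceed")
})

test_that("pSILAC split follows the half-life law", {
  truth <- generate_truth(20, rbp_cfg = NULL, seed = 2)
  expect_true(all(simulate_psilac_split(truth, 0) == 0))
  half <- truth$turnover_halflife
  expect_equal(unname(simulate_psilac_split(truth, half[1])[1]), 0.5)
  expect_equal(unname(simulate_psilac_split(c(h = 8), 16)), 0.75)
  # strictly increasing in t, in [0, 1)
  h4 <- simulate_psilac_split(truth, 4)
  h16 <- simulate_psilac_split(truth, 16)
  expect_true(all(h16 > h4))
  expect_true(all(h4 >= 0 & h16 < 1))
  expect_error(simulate_psilac_split(c(-1, 3), 4), "positive")
  expect_error(simulate_psilac_split(truth, -1), ">= 0")
})

test_that("noise-free protein fractions reproduce planted weight ratios", {
  truth <- generate_truth(50, rbp_cfg = NULL, seed = 13)
  sc <- default_fraction_scheme()
  tab <- simulate_protein_fractions(truth, sc, noise_config())
  expect_true(all(tab$abundance >= 0))
  # conservation: per protein/condition, fractions x channels sum to base
  sums <- tapply(tab$abundance, list(tab$protein_id, tab$condition), sum)
  expect_equal(unname(sums[truth$entity_id, "normoxia"]),
               truth$base_abundance, tolerance = 1e-12)
  en <- engagement_ratios(filter_silac(tab), sc, "hypoxia")
  i <- match(en$protein_id, truth$entity_id)
  expect_equal(en$pf_ratio, truth$w_poly_hypoxia[i] / truth$w_free_hypoxia[i],
               tolerance = 1e-9)
  expect_equal(en$pm_ratio, truth$w_poly_hypoxia[i] / truth$w_mono_hypoxia[i],
               tolerance = 1e-9)
})

test_that("seeded regeneration of noisy tables is identical", {
  truth <- generate_truth(30, rbp_cfg = NULL, seed = 4)
  n <- noise_config(lognormal_sigma = 0.1, seed = 77)
  tabs <- replicate(3, simulate_protein_fractions(truth, noise = n),
                    simplify = FALSE)
  expect_identical(tabs[[1]], tabs[[2]])
  expect_identical(tabs[[2]], tabs[[3]])
})

test_that("TMT compression follows the power law", {
  # single entity with planted ratio 2.0 (class III), kappa = 0.5
  truth <- generate_truth(200, rbp_cfg = NULL, seed = 15)
  tmt_k1 <- simulate_tmt(truth, noise = noise_config(tmt_kappa = 1))
  tmt_k05 <- simulate_tmt(truth, noise = noise_config(tmt_kappa = 0.5))
  r1 <- with(tmt_k1, intensity[sample_id == "hypoxia_NS"] /
               intensity[sample_id == "normoxia_NS"])
  r05 <- with(tmt_k05, intensity[sample_id == "hypoxia_NS"] /
                intensity[sample_id == "normoxia_NS"])
  expect_equal(r1, truth$output_ratio, tolerance = 1e-12)
  expect_equal(r05, truth$output_ratio^0.5, tolerance = 1e-12)
  # true ratio 1 is a fixed point for any kappa
  ones <- which(abs(r1 - 1) < 1e-9)
  expect_equal(r05[ones], r1[ones], tolerance = 1e-9)
})

test_that("TMT design validation catches missing NS and unknown effects", {
  truth <- generate_truth(20, rbp_cfg = NULL, seed = 6)
  bad <- data.frame(sample_id = "s1", condition = "hypoxia",
                    perturbation = "HuR")
  expect_error(simulate_tmt(truth, bad), "no NS sample")
  ok_design <- tmt_design("GhostRBP")
  expect_error(simulate_tmt(truth, ok_design), "GhostRBP")
})

test_that("planted siRBP effect is called dependent on noise-free output", {
  # 0.8 effect in a 6-channel design: relative output 0.8/0.9667 ~ 0.83
  cfg <- rbp_config(portfolios = c(HuR = 30, R2 = 0, R3 = 0, R4 = 0, R5 = 0),
                    output_effect = 0.80)
  truth <- generate_truth(300, rbp_cfg = cfg, seed = 31)
  res <- classify_translatome(simulate_tmt(truth))
  expect_identical(res$portfolios$HuR, truth_portfolios(truth)$HuR)
  # non-targets stay uncalled
  expect_null(res$portfolios$R2)
})

test_that("ribosome-load model gives monotone TE and degenerate cases", {
  expect_identical(te_from_load(0), 0)
  lam <- seq(0.2, 8, by = 0.2)
  expect_true(all(diff(te_from_load(lam)) > 0))
  # inversion round trip
  l2 <- load_for_te_ratio(2, 0.25)
  expect_equal(te_from_load(l2), 0.25 * te_from_load(2), tolerance = 1e-9)
  expect_identical(load_for_te_ratio(2, 0), 0)
  expect_identical(load_for_te_ratio(2, 1), 2)
})

test_that("fraction counts: degenerate load, monotonicity, exact noise-free", {
  sc <- default_fraction_scheme()
  truth <- generate_truth(40, rbp_cfg = NULL, seed = 9)
  truth$lambda_hypoxia[1] <- 0        # all mass in free fractions
  cs <- simulate_fraction_counts(truth, sc, noise_config(),
                                 samples = data.frame(sample_id = "NS",
                                                      perturbation = "NS"),
                                 depth_model = "mass")
  te <- te_table(cs$fpkm, sc)
  g1 <- te[te$gene_id == truth$entity_id[1], ]
  expect_equal(g1$te, 0)
  # genes identical except lambda: TE strictly ordered by lambda
  i <- match(te$gene_id, truth$entity_id)
  ord <- order(truth$lambda_hypoxia[i])
  expect_true(all(diff(te$te[ord]) > 0))
  expect_equal(te$te, te_from_load(truth$lambda_hypoxia[i]), tolerance = 1e-9)
  # dispersion 0: counts equal rounded expectations (integers)
  expect_true(all(cs$counts$count == round(cs$counts$count)))
})

test_that("fraction counts are reproducible and NB noise is seeded", {
  truth <- generate_truth(25, rbp_cfg = NULL, seed = 3)
  n <- noise_config(nb_dispersion = 0.1, library_size = 1e5, seed = 12)
  a <- simulate_fraction_counts(truth, noise = n)
  b <- simulate_fraction_counts(truth, noise = n)
  expect_identical(a$counts, b$counts)
  c <- simulate_fraction_counts(truth,
                                noise = noise_config(nb_dispersion = 0.1,
                                                     library_size = 1e5,
                                                     seed = 13))
  expect_false(identical(a$counts$count, c$counts$count))
})

test_that("noise_config validates parameter ranges", {
  expect_error(noise_config(lognormal_sigma = -1), "lognormal_sigma")
  expect_error(noise_config(tmt_kappa = 0), "tmt_kappa")
  expect_error(noise_config(tmt_kappa = 1.2), "tmt_kappa")
  expect_error(noise_config(nb_dispersion = -0.1), "nb_dispersion")
  expect_error(noise_config(library_size = 0), "library_size")
})

test_that("emit_dataset round-trips tables and checksums are stable", {
  dir <- withr::local_tempdir()
  truth <- generate_truth(15, rbp_cfg = NULL, seed = 2)
  tab <- simulate_protein_fractions(truth, noise = noise_config(
    lognormal_sigma = 0.2, seed = 5))
  m1 <- emit_dataset(list(proteins_fractions = tab), dir,
                     config = list(n = 15), seed = 2)
  back <- read_protein_fraction_table(file.path(dir, "proteins_fractions.tsv"))
  expect_identical(back$abundance, tab$abundance)
  expect_identical(back$protein_id, tab$protein_id)
  m2 <- emit_dataset(list(proteins_fractions = tab), dir)
  expect_identical(m1$md5, m2$md5)
  expect_error(emit_dataset(list(x = tab), file.path(dir, "missing_subdir")),
               "missing_subdir")
})
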