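# TE / steady-state RNA / delta quadrants / polysome AUC / comparative Ct.

test_that("translation efficiency is the polysome over free+monosome ratio", {
  sc <- tiny_scheme()
  # polysome 10, free 2, monosome 3 -> TE = 2
  te <- translation_efficiency(c(2, 3, 6, 4), c("F", "M", "P2", "P5"), sc)
  expect_equal(te, 2)
  # free-only denominator option
  expect_equal(translation_efficiency(c(2, 3, 6, 4), c("F", "M", "P2", "P5"),
                                      sc, denominator = "free"), 5)
  # all signal polysomal: undefined at zero pseudocount
  expect_true(is.na(translation_efficiency(c(0, 0, 5, 5),
                                           c("F", "M", "P2", "P5"), sc)))
  # scale invariance
  expect_equal(translation_efficiency(7 * c(2, 3, 6, 4),
                                      c("F", "M", "P2", "P5"), sc), 2)
  expect_error(translation_efficiency(c(-1, 3, 6, 4),
                                      c("F", "M", "P2", "P5"), sc),
               "non-negative")
})

test_that("steady-state RNA is the order-invariant fraction sum", {
  expect_equal(steady_state_rna(c(1, 2, 3, 4)), 10)
  expect_equal(steady_state_rna(rep(0, 5)), 0)
  expect_equal(steady_state_rna(c(4, 1, 3, 2)), 10)
})

test_that("te_table matches per-gene computation and flags undefined TE", {
  sc <- tiny_scheme()
  fpkm <- data.frame(
    gene_id = rep(c("g1", "g2"), each = 4),
    sample_id = "NS",
    fraction_id = rep(c("F", "M", "P2", "P5"), 2),
    fpkm = c(2, 3, 6, 4, 0, 0, 5, 5),
    stringsAsFactors = FALSE
  )
  te <- te_table(fpkm, sc)
  expect_equal(te$te[te$gene_id == "g1"], 2)
  expect_true(is.na(te$te[te$gene_id == "g2"]))
  expect_false(te$te_defined[te$gene_id == "g2"])
  expect_equal(te$steady_state_rna, c(15, 10))
})

test_that("delta classification applies the inclusive two-fold rule", {
  d <- delta_classification(
    te_kd = c(0.4, 0.5, 0.45, 1, 3) , te_ns = rep(1, 5),
    rna_kd = c(0.9, 1, 2.2, 0.4, 2), rna_ns = rep(1, 5))
  expect_identical(d$quadrant,
                   c("te_only", "te_only", "both", "rna_only", "both"))
  expect_identical(d$direction, c("down", "down", "mixed", "down", "up"))
  # exact boundaries significant (inclusive)
  b <- delta_classification(c(2, 0.5, 1.999), rep(1, 3),
                            rep(1, 3), rep(1, 3))
  expect_identical(b$te_significant, c(TRUE, TRUE, FALSE))
  expect_error(delta_classification(1, 1, 1, 1, fold_threshold = 1),
               "fold_threshold")
  # ratio invariance under common rescaling of both samples
  d1 <- delta_classification(3, 6, 10, 20)
  d2 <- delta_classification(3 * 5, 6 * 5, 10 * 5, 20 * 5)
  expect_equal(d1$delta_te, d2$delta_te)
  expect_equal(d1$delta_rna, d2$delta_rna)
})

test_that("quadrant partition and marginals are conserved", {
  set.seed(101)
  n <- 400
  d <- delta_classification(te_kd = exp(rnorm(n)), te_ns = rep(1, n),
                            rna_kd = exp(rnorm(n)), rna_ns = rep(1, n))
  d$gene_id <- sprintf("g%03d", seq_len(n))
  qs <- quadrant_summary(d)
  expect_equal(sum(qs$counts), n)
  expect_equal(qs$te_affected, sum(d$te_significant))
  expect_equal(qs$rna_affected, sum(d$rna_significant))
})

test_that("delta_table filters low expression and reports unclassifiable", {
  sc <- tiny_scheme()
  fpkm <- data.frame(
    gene_id = rep(c("g1", "g2"), each = 8),
    sample_id = rep(rep(c("NS", "siX"), each = 4), 2),
    fraction_id = rep(c("F", "M", "P2", "P5"), 4),
    fpkm = c(2, 3, 6, 4, 2, 3, 4, 1,      # g1: TE 2 -> 1, dTE = 0.5 exactly
             0.1, 0.1, 0.2, 0.1, 0.1, 0.1, 0.2, 0.1),  # g2 below min expr
    stringsAsFactors = FALSE
  )
  te <- te_table(fpkm, sc)
  d <- delta_table(te, "NS", "siX", min_expression = 1)
  expect_identical(d$gene_id, "g1")
  expect_equal(d$delta_te, 0.5)
  expect_true(d$te_significant)   # inclusive boundary
  unc <- attr(d, "unclassifiable")
  expect_identical(unc$gene_id, "g2")
  expect_match(unc$reason, "minimum expression")
})

test_that("magnitude summaries use geometric and arithmetic means", {
  d <- list(delta_te = c(0.5, 0.5, 0.5), delta_rna = c(1, 1, 1))
  m <- summarize_magnitudes(d)
  expect_equal(m["te", "percent_decrease_geometric"], 50)
  expect_equal(m["rna", "percent_decrease_geometric"], 0)
  m2 <- summarize_magnitudes(list(delta_te = c(0.25, 1), delta_rna = 1))
  expect_equal(m2["te", "percent_decrease_geometric"], 50)
  expect_equal(m2["te", "percent_decrease_arithmetic"], 100 * (1 - 0.625))
  expect_error(summarize_magnitudes(list(delta_te = numeric(0),
                                         delta_rna = 1)), "te")
})

test_that("polysome AUC matches analytic integrals", {
  # uniform signal, boundary at midpoint
  expect_equal(polysome_auc(0:10, rep(2, 11), 5), 0.5, tolerance = 1e-9)
  # triangular ramp y = x on [0, 1], boundary 0.5: 0.375/0.5
  x <- seq(0, 1, by = 0.05)
  expect_equal(polysome_auc(x, x, 0.5), 0.75, tolerance = 1e-9)
  # boundary between sample points (interpolated): same analytic answer
  x2 <- c(0, 0.3, 0.8, 1)
  expect_equal(polysome_auc(x2, x2, 0.5), 0.75, tolerance = 1e-9)
  # all signal strictly before the boundary
  expect_equal(polysome_auc(c(0, 1, 2, 3), c(1, 1, 0, 0), 2.5), 0)
  # scale invariance and monotone rightward shift
  expect_equal(polysome_auc(x, 13 * x, 0.5), polysome_auc(x, x, 0.5))
  expect_gt(polysome_auc(x, x^2, 0.5), polysome_auc(x, x, 0.5))
  expect_warning(v <- polysome_auc(0:3, rep(0, 4), 1), "zero")
  expect_true(is.na(v))
  expect_error(polysome_auc(0:3, rep(1, 4), 9), "range")
  expect_error(polysome_auc(1, 1, 1), ">= 2")
})

test_that("comparative Ct reproduces closed forms", {
  expect_equal(ddct(20, 15, 20, 15), 1)
  # target one cycle lower in test, references equal
  expect_equal(ddct(19, 15, 20, 15), 2)
  # ddCt = log2(10) -> fold 0.1
  expect_equal(ddct(15 + log2(10), 15, 20, 20), 0.1, tolerance = 1e-12)
  expect_error(ddct(NA, 1, 1, 1), "finite")
})
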