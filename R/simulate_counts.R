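# Ribosome-load model and fraction-level RNA-seq count/FPKM simulation.

# Truncated-Poisson probability of each ribosome count 0..kmax, with the tail
# P(k >= kmax) lumped into kmax.
load_pmf <- function(lambda, kmax) {
  p <- stats::dpois(0:(kmax - 1), lambda)
  c(p, max(0, 1 - sum(p)))
}

#' Expected translation efficiency of a ribosome load
#'
#' Under the generator's load model, transcripts of a gene carry
#' `k ~ Poisson(lambda)` ribosomes (tail lumped at `kmax`); `k = 0` transcripts
#' sediment in free fractions, `k = 1` in monosome fractions, and `k >= 2` in
#' polysome fractions. The expected translation efficiency is therefore
#' `P(k >= 2) / P(k <= 1)`, strictly increasing in `lambda` and 0 at
#' `lambda = 0`.
#'
#' @param lambda Mean ribosomes per transcript (>= 0), vectorized.
#' @param kmax Maximum resolved ribosome count.
#' @return Expected polysome/(free+monosome) mass ratio.
#' @export
te_from_load <- function(lambda, kmax = 8L) {
  if (any(lambda < 0)) stop("`lambda` must be >= 0")
  vapply(lambda, function(l) {
    p01 <- stats::dpois(0, l) + stats::dpois(1, l)
    (1 - p01) / p01
  }, numeric(1))
}

#' Ribosome load realizing a planted translation-efficiency ratio
#'
#' Solves for `lambda2` such that
#' `te_from_load(lambda2) = ratio * te_from_load(lambda)`. Used to plant
#' knockdown/control or hypoxia/normoxia TE shifts in the generator.
#'
#' @param lambda Baseline load (> 0 unless `ratio` is irrelevant).
#' @param ratio Target TE ratio (>= 0); 0 maps to `lambda2 = 0`.
#' @param kmax Maximum resolved ribosome count (monotonicity bound only).
#' @return The adjusted load.
#' @export
load_for_te_ratio <- function(lambda, ratio, kmax = 8L) {
  if (ratio < 0) stop("`ratio` must be >= 0")
  if (ratio == 1 || lambda == 0) return(lambda)
  target <- te_from_load(lambda, kmax) * ratio
  if (target == 0) return(0)
  upper <- max(lambda, 1)
  while (te_from_load(upper, kmax) < target && upper < 1e3) upper <- upper * 2
  stats::uniroot(function(l) te_from_load(l, kmax) - target,
                 lower = 0, upper = upper, tol = 1e-12)$root
}

#' Simulate fraction-level RNA-seq counts and FPKM
#'
#' For each gene and sample, transcript mass is distributed over gradient
#' fractions by the truncated-Poisson ribosome-load model: `k = 0` mass goes
#' uniformly to free fractions, `k = 1` to monosome fractions, and `k >= 2` to
#' the polysome fraction annotated with that ribosome count (tail lumped at
#' the scheme's maximum). Knockdown samples scale each target gene's
#' steady-state mass by the planted RNA effect and shift its load so the
#' expected TE ratio to control equals the planted TE effect.
#'
#' Sequencing is emulated per fraction: expected counts are the gene's share
#' of the fraction's mass scaled to `library_size` reads
#' (`depth_model = "equal"`, the default) or to a depth proportional to the
#' fraction's total mass (`depth_model = "mass"`). Counts are negative
#' binomial around the expectation; at `nb_dispersion = 0` they equal the
#' (rounded) expectation and FPKM is computed from the exact expectation.
#' FPKM divides counts by gene length (kb) times millions of mapped reads in
#' the fraction under `"equal"`, or millions of mapped reads in the whole
#' sample under `"mass"`. The `"mass"` model makes FPKM proportional to
#' transcript mass, so planted TE ratios are recovered exactly in the
#' noise-free regime; the `"equal"` model reproduces the compositional bias of
#' fixed per-fraction sequencing depth.
#'
#' @param truth A `truth_table`.
#' @param scheme A `fraction_scheme` whose polysome fractions carry ribosome
#'   counts (unannotated polysome fractions receive the `k >= 2` mass
#'   uniformly).
#' @param noise A `noise_config` (uses `nb_dispersion`, `library_size`,
#'   `seed`).
#' @param samples Data frame `sample_id, perturbation` (`"NS"` or an RBP with
#'   planted effects). Default: NS plus one knockdown per truth-table RBP.
#' @param condition Condition whose planted loads are used (default
#'   `"hypoxia"`, where knockdown RNomics is typically performed).
#' @param gene_length_kb Per-gene transcript length in kb; defaults to the
#'   truth table's.
#' @param depth_model `"equal"` or `"mass"` (see above).
#' @return A list of class `fraction_sim`: `fpkm` (a `fraction_fpkm_table`
#'   data frame: `gene_id, sample_id, fraction_id, fpkm`), `counts` (same
#'   shape, integer counts), `true_te` (planted expected TE per gene and
#'   sample), and `samples`.
#' @export
simulate_fraction_counts <- function(truth, scheme = default_fraction_scheme(),
                                     noise = noise_config(), samples = NULL,
                                     condition = "hypoxia",
                                     gene_length_kb = NULL,
                                     depth_model = c("equal", "mass")) {
  stopifnot(inherits(truth, "truth_table"), inherits(scheme, "fraction_scheme"),
            inherits(noise, "noise_config"))
  depth_model <- match.arg(depth_model)
  if (is.null(samples)) {
    rbps <- attr(truth, "rbps")
    samples <- data.frame(
      sample_id = c("NS", if (length(rbps)) paste0("si", rbps)),
      perturbation = c("NS", rbps),
      stringsAsFactors = FALSE
    )
  }
  if (is.null(gene_length_kb)) gene_length_kb <- truth$gene_length_kb
  if (any(gene_length_kb <= 0)) stop("gene lengths must be positive")
  kmax <- max_ribosome_count(scheme)
  if (is.na(kmax)) kmax <- 8L
  lambda0 <- truth[[paste0("lambda_", condition)]]
  if (is.null(lambda0)) stop("truth table has no loads for condition ", condition)

  frac_ids <- scheme$fraction_ids
  comp_of <- scheme$compartment[frac_ids]
  free_ix <- which(comp_of == "free")
  mono_ix <- which(comp_of == "monosome")
  poly_ix <- which(comp_of == "polysome")
  rc <- scheme$ribosome_count[frac_ids]
  # rows of the mass-allocation matrix: ribosome count 0..kmax -> fractions
  alloc <- matrix(0, nrow = kmax + 1, ncol = length(frac_ids))
  alloc[1, free_ix] <- 1 / length(free_ix)
  alloc[2, mono_ix] <- 1 / length(mono_ix)
  poly_rc <- rc[poly_ix]
  if (all(is.na(poly_rc))) {
    alloc[3:(kmax + 1), poly_ix] <- 1 / length(poly_ix)
  } else {
    for (k in 2:kmax) {
      hit <- poly_ix[!is.na(poly_rc) & poly_rc == k]
      if (!length(hit)) { # unannotated count: nearest annotated fraction
        hit <- poly_ix[which.min(abs(poly_rc - k))]
      }
      alloc[k + 1, hit] <- 1 / length(hit)
    }
  }

  ng <- nrow(truth)
  fpkm_blocks <- counts_blocks <- vector("list", nrow(samples))
  true_te <- vector("list", nrow(samples))
  with_seed(noise$seed, offset = 303L, {
    for (s in seq_len(nrow(samples))) {
      pert <- samples$perturbation[s]
      lam <- lambda0
      abund <- truth$base_abundance
      if (pert != "NS") {
        te_col <- paste0("te_effect_", pert)
        rna_col <- paste0("rna_effect_", pert)
        if (!te_col %in% names(truth)) {
          stop("truth table has no planted effects for perturbation ", pert)
        }
        lam <- vapply(seq_len(ng), function(i) {
          load_for_te_ratio(lambda0[i], truth[[te_col]][i], kmax)
        }, numeric(1))
        abund <- abund * truth[[rna_col]]
      }
      pmf <- t(vapply(lam, load_pmf, numeric(kmax + 1), kmax = kmax))
      mass <- (pmf %*% alloc) * abund          # gene x fraction
      te_true <- te_from_load(lam, kmax)

      tot <- colSums(mass)
      if (depth_model == "equal") {
        mu <- sweep(mass, 2, ifelse(tot > 0, tot, 1), "/") * noise$library_size
        mu[, tot == 0] <- 0
      } else {
        mu <- mass / sum(mass) * noise$library_size * length(frac_ids)
      }
      if (noise$nb_dispersion > 0) {
        cnt <- matrix(stats::rnbinom(length(mu), mu = mu,
                                     size = 1 / noise$nb_dispersion),
                      nrow = ng)
        basis <- cnt
      } else {
        cnt <- round(mu)
        basis <- mu  # exact expectation keeps the noise-free regime exact
      }
      if (depth_model == "equal") {
        mapped <- colSums(basis) / 1e6
        denom <- outer(gene_length_kb, ifelse(mapped > 0, mapped, 1))
        fpkm <- basis / denom
        fpkm[, mapped == 0] <- 0
      } else {
        mapped <- sum(basis) / 1e6
        fpkm <- basis / (gene_length_kb * mapped)
      }
      fpkm_blocks[[s]] <- data.frame(
        gene_id = rep(truth$entity_id, times = length(frac_ids)),
        sample_id = samples$sample_id[s],
        fraction_id = rep(frac_ids, each = ng),
        fpkm = as.vector(fpkm),
        stringsAsFactors = FALSE
      )
      counts_blocks[[s]] <- data.frame(
        gene_id = rep(truth$entity_id, times = length(frac_ids)),
        sample_id = samples$sample_id[s],
        fraction_id = rep(frac_ids, each = ng),
        count = as.vector(cnt),
        stringsAsFactors = FALSE
      )
      true_te[[s]] <- data.frame(gene_id = truth$entity_id,
                                 sample_id = samples$sample_id[s],
                                 te = te_true, stringsAsFactors = FALSE)
    }
  })
  fpkm <- do.call(rbind, fpkm_blocks)
  rownames(fpkm) <- NULL
  class(fpkm) <- c("fraction_fpkm_table", "data.frame")
  counts <- do.call(rbind, counts_blocks)
  rownames(counts) <- NULL
  structure(list(fpkm = fpkm, counts = counts,
                 true_te = do.call(rbind, true_te), samples = samples),
            class = "fraction_sim")
}
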