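# Fraction-level RNA-seq analysis: translation efficiency, steady-state RNA,
# knockdown delta classification, polysome AUC, and comparative Ct.

#' Translation efficiency of one gene
#'
#' TE is the ratio of FPKM summed over polysome fractions to FPKM summed over
#' free and monosome fractions: polysomal (productive) signal relative to
#' untranslated/initiating signal. A zero denominator (with `pseudocount = 0`,
#' the default) leaves TE undefined (NA).
#'
#' @param fpkm Non-negative numeric vector of per-fraction FPKM.
#' @param fraction_ids Fraction ids aligned with `fpkm`.
#' @param scheme A `fraction_scheme` covering those fractions.
#' @param pseudocount Added to numerator and denominator (default 0).
#' @param denominator `"free_mono"` (default) or `"free"`.
#' @return A single TE value, NA if undefined.
#' @export
translation_efficiency <- function(fpkm, fraction_ids, scheme,
                                   pseudocount = 0,
                                   denominator = c("free_mono", "free")) {
  denominator <- match.arg(denominator)
  if (any(fpkm < 0)) stop("FPKM values must be non-negative")
  assert_fractions_known(scheme, fraction_ids)
  comp <- scheme$compartment[as.character(fraction_ids)]
  num <- sum(fpkm[comp == "polysome"]) + pseudocount
  den <- sum(fpkm[comp == "free"]) + pseudocount
  if (denominator == "free_mono") den <- den + sum(fpkm[comp == "monosome"])
  if (den <= 0) return(NA_real_)
  num / den
}

#' Steady-state RNA level of one gene
#'
#' The aggregate (sum) of FPKM across all gradient fractions; invariant to
#' fraction order.
#'
#' @param fpkm Non-negative numeric vector of per-fraction FPKM.
#' @return Total FPKM.
#' @export
steady_state_rna <- function(fpkm) {
  if (any(fpkm < 0)) stop("FPKM values must be non-negative")
  sum(fpkm)
}

#' Per-gene TE and steady-state RNA for every sample
#'
#' @param fpkm_table A `fraction_fpkm_table`-shaped data frame with columns
#'   `gene_id, sample_id, fraction_id, fpkm`.
#' @param scheme A `fraction_scheme`.
#' @param pseudocount,denominator Passed to [translation_efficiency()].
#' @return Data frame `gene_id, sample_id, te, te_defined, steady_state_rna`.
#' @export
te_table <- function(fpkm_table, scheme, pseudocount = 0,
                     denominator = c("free_mono", "free")) {
  denominator <- match.arg(denominator)
  if (any(fpkm_table$fpkm < 0)) stop("FPKM values must be non-negative")
  assert_fractions_known(scheme, fpkm_table$fraction_id)
  comp <- scheme$compartment[fpkm_table$fraction_id]
  key <- list(gene = fpkm_table$gene_id, sample = fpkm_table$sample_id)
  poly <- tapply(fpkm_table$fpkm * (comp == "polysome"), key, sum)
  den <- tapply(fpkm_table$fpkm * (comp == "free"), key, sum)
  if (denominator == "free_mono") {
    den <- den + tapply(fpkm_table$fpkm * (comp == "monosome"), key, sum)
  }
  total <- tapply(fpkm_table$fpkm, key, sum)
  genes <- rownames(poly); samples <- colnames(poly)
  num <- as.vector(poly) + pseudocount
  dnm <- as.vector(den) + pseudocount
  out <- data.frame(
    gene_id = rep(genes, times = length(samples)),
    sample_id = rep(samples, each = length(genes)),
    te = ifelse(dnm > 0, num / dnm, NA_real_),
    te_defined = dnm > 0,
    steady_state_rna = as.vector(total),
    stringsAsFactors = FALSE
  )
  out <- out[!is.na(out$steady_state_rna), , drop = FALSE]  # absent pairs
  rownames(out) <- NULL
  out
}

#' Classify knockdown effects into regulatory quadrants
#'
#' Forms `delta_te = te_kd / te_ns` and `delta_rna = rna_kd / rna_ns`; a delta
#' is significant iff it is `>= fold_threshold` or `<= 1/fold_threshold`
#' (inclusive two-fold rule by default). The two significance flags define the
#' quadrant (`te_only`, `rna_only`, `both`, `neither`) and the sign pattern
#' the direction (`up`, `down`, `mixed`; `none` for `neither`).
#'
#' @param te_kd,te_ns,rna_kd,rna_ns Numeric vectors (NS values must be
#'   positive; NA TE marks the gene unclassifiable).
#' @param fold_threshold Fold-change threshold (> 1), default 2.
#' @return Data frame `delta_te, delta_rna, te_significant, rna_significant,
#'   quadrant, direction`; unclassifiable genes carry quadrant NA.
#' @export
delta_classification <- function(te_kd, te_ns, rna_kd, rna_ns,
                                 fold_threshold = 2) {
  if (!is.numeric(fold_threshold) || length(fold_threshold) != 1 ||
      is.na(fold_threshold) || fold_threshold <= 1) {
    stop("`fold_threshold` must be a single number > 1")
  }
  n <- length(te_kd)
  ok <- !is.na(te_kd) & !is.na(te_ns) & te_ns > 0 & rna_ns > 0
  delta_te <- ifelse(ok, te_kd / te_ns, NA_real_)
  delta_rna <- ifelse(ok, rna_kd / rna_ns, NA_real_)
  sig <- function(d) !is.na(d) & (d >= fold_threshold | d <= 1 / fold_threshold)
  te_sig <- sig(delta_te); rna_sig <- sig(delta_rna)
  quadrant <- rep(NA_character_, n)
  quadrant[ok] <- ifelse(te_sig[ok] & rna_sig[ok], "both",
                  ifelse(te_sig[ok], "te_only",
                  ifelse(rna_sig[ok], "rna_only", "neither")))
  dir_of <- function(d) ifelse(d > 1, "up", "down")
  direction <- rep(NA_character_, n)
  direction[ok] <- "none"
  i <- which(quadrant == "te_only"); direction[i] <- dir_of(delta_te[i])
  i <- which(quadrant == "rna_only"); direction[i] <- dir_of(delta_rna[i])
  i <- which(quadrant == "both")
  direction[i] <- ifelse(dir_of(delta_te[i]) == dir_of(delta_rna[i]),
                         dir_of(delta_te[i]), "mixed")
  data.frame(delta_te = delta_te, delta_rna = delta_rna,
             te_significant = te_sig, rna_significant = rna_sig,
             quadrant = quadrant, direction = direction,
             stringsAsFactors = FALSE)
}

#' Knockdown-versus-control delta table for all genes
#'
#' Joins the TE records of a knockdown and an NS control sample, applies a
#' minimum-expression filter on the NS steady-state RNA (ratio stability), and
#' classifies every gene into a regulatory quadrant. Genes failing the filter
#' or with undefined TE are routed to the `"unclassifiable"` attribute with a
#' reason.
#'
#' @param te_records Output of [te_table()] covering both samples.
#' @param ns_sample,kd_sample Sample ids of control and knockdown.
#' @param fold_threshold Two-sided fold threshold, default 2.
#' @param min_expression Minimum NS steady-state FPKM (default 1).
#' @return Data frame `gene_id, delta_te, delta_rna, te_significant,
#'   rna_significant, quadrant, direction` for classifiable genes, with
#'   attribute `unclassifiable`.
#' @export
delta_table <- function(te_records, ns_sample, kd_sample,
                        fold_threshold = 2, min_expression = 1) {
  ns <- te_records[te_records$sample_id == ns_sample, , drop = FALSE]
  kd <- te_records[te_records$sample_id == kd_sample, , drop = FALSE]
  if (!nrow(ns)) stop("no TE records for NS sample ", ns_sample)
  if (!nrow(kd)) stop("no TE records for knockdown sample ", kd_sample)
  shared <- intersect(ns$gene_id, kd$gene_id)
  ns <- ns[match(shared, ns$gene_id), ]
  kd <- kd[match(shared, kd$gene_id), ]

  reason <- rep(NA_character_, length(shared))
  reason[ns$steady_state_rna < min_expression] <- "below minimum expression"
  reason[is.na(reason) &
           (!ns$te_defined | !kd$te_defined)] <- "undefined TE"
  reason[is.na(reason) &
           (ns$te <= 0 | ns$steady_state_rna <= 0)] <- "zero NS denominator"
  keep <- is.na(reason)
  unclassifiable <- data.frame(gene_id = shared[!keep],
                               reason = reason[!keep],
                               stringsAsFactors = FALSE)
  cls <- delta_classification(kd$te[keep], ns$te[keep],
                              kd$steady_state_rna[keep],
                              ns$steady_state_rna[keep],
                              fold_threshold)
  out <- cbind(data.frame(gene_id = shared[keep], stringsAsFactors = FALSE),
               cls)
  rownames(out) <- NULL
  attr(out, "unclassifiable") <- unclassifiable
  out
}

#' Quadrant counts and affected marginals
#'
#' @param deltas A delta table from [delta_table()].
#' @return List with `counts` (named quadrant counts), `te_affected`
#'   (`te_only + both`), `rna_affected` (`rna_only + both`) and
#'   `n_classifiable`.
#' @export
quadrant_summary <- function(deltas) {
  q <- table(factor(deltas$quadrant,
                    c("te_only", "rna_only", "both", "neither")))
  counts <- stats::setNames(as.integer(q), names(q))
  list(counts = counts,
       te_affected = counts[["te_only"]] + counts[["both"]],
       rna_affected = counts[["rna_only"]] + counts[["both"]],
       n_classifiable = sum(counts))
}

#' Mean/median percent change of delta ratios
#'
#' Per axis (TE and RNA), reports the percent decrease implied by the
#' geometric mean of the ratios, `100 * (1 - exp(mean(log r)))`, alongside the
#' arithmetic-mean variant and the median ratio.
#'
#' @param deltas A delta table (uses `delta_te` and `delta_rna`), or a list
#'   with those elements.
#' @return Data frame with rows `te` and `rna` and columns
#'   `percent_decrease_geometric, percent_decrease_arithmetic, median_ratio,
#'   n`.
#' @export
summarize_magnitudes <- function(deltas) {
  axes <- list(te = deltas$delta_te, rna = deltas$delta_rna)
  rows <- lapply(names(axes), function(a) {
    r <- axes[[a]]
    r <- r[!is.na(r)]
    if (!length(r)) stop("no defined ratios for axis ", a)
    if (any(r <= 0)) stop("ratios must be positive for axis ", a)
    data.frame(axis = a,
               percent_decrease_geometric = 100 * (1 - exp(mean(log(r)))),
               percent_decrease_arithmetic = 100 * (1 - mean(r)),
               median_ratio = stats::median(r),
               n = length(r),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- out$axis
  out
}

#' Polysome proportion of a ribosome-density trace
#'
#' Trapezoidal area of the trace at positions at or beyond the heavy-polysome
#' boundary (nominally the >= 5-ribosome mark), divided by the total
#' trapezoidal area. The signal is linearly interpolated at the boundary when
#' it falls between sampled positions. Invariant to uniform signal scaling.
#'
#' @param position Ordered numeric abscissa (fraction index or gradient
#'   depth), at least 2 points.
#' @param signal Non-negative trace values at `position`.
#' @param boundary Position of the polysome boundary, within the abscissa
#'   range.
#' @return Proportion in `[0, 1]`; NA (with a warning) if total area is zero.
#' @export
polysome_auc <- function(position, signal, boundary) {
  if (length(position) < 2 || length(position) != length(signal)) {
    stop("need >= 2 (position, signal) points of equal length")
  }
  if (any(signal < 0)) stop("signal must be non-negative")
  if (boundary < min(position) || boundary > max(position)) {
    stop("boundary must lie within the position range")
  }
  ord <- order(position)
  x <- position[ord]; y <- signal[ord]
  if (!boundary %in% x) {
    yb <- stats::approx(x, y, xout = boundary)$y
    i <- findInterval(boundary, x)
    x <- append(x, boundary, after = i)
    y <- append(y, yb, after = i)
  }
  trap <- function(x, y) {
    if (length(x) < 2) return(0)
    sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  }
  total <- trap(x, y)
  if (total <= 0) {
    warning("total trace area is zero; polysome proportion undefined")
    return(NA_real_)
  }
  sel <- x >= boundary
  trap(x[sel], y[sel]) / total
}

#' Comparative Ct (delta-delta-Ct) fold change
#'
#' `fold = 2^-((Ct_target,test - Ct_reference,test) -
#' (Ct_target,calibrator - Ct_reference,calibrator))`, the standard relative
#' qRT-PCR quantification with an internal reference (e.g., 18S rRNA) and a
#' calibrator sample (e.g., NS control).
#'
#' @param ct_target_test,ct_reference_test Ct values in the test sample.
#' @param ct_target_calibrator,ct_reference_calibrator Ct values in the
#'   calibrator sample.
#' @return Fold change (vectorized).
#' @export
ddct <- function(ct_target_test, ct_reference_test,
                 ct_target_calibrator, ct_reference_calibrator) {
  vals <- c(ct_target_test, ct_reference_test,
            ct_target_calibrator, ct_reference_calibrator)
  if (any(!is.finite(vals))) stop("Ct values must be finite")
  ddct <- (ct_target_test - ct_reference_test) -
    (ct_target_calibrator - ct_reference_calibrator)
  2^(-ddct)
}
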