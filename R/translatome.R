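# TMT pulse-SILAC protein-output analysis: channel normalization, relative
# output, oxygen-response classes, RBP dependency calls, and class-composition
# chi-square tests.

#' Total-intensity channel normalization
#'
#' Rescales every TMT channel (sample) so that all channel totals equal the
#' grand mean of the original totals: a loading correction that preserves
#' within-channel structure and is idempotent.
#'
#' @param experiment A `tmt_experiment`-shaped data frame with columns
#'   `protein_id, sample_id, condition, perturbation, intensity`.
#' @return The experiment with rescaled intensities.
#' @export
tmt_total_normalize <- function(experiment) {
  totals <- tapply(experiment$intensity, experiment$sample_id, sum)
  if (any(totals == 0)) {
    stop("channel(s) with zero total intensity: ",
         paste(names(totals)[totals == 0], collapse = ", "))
  }
  scale <- mean(totals) / totals
  experiment$intensity <- as.numeric(experiment$intensity *
                                       scale[experiment$sample_id])
  experiment
}

#' Relative protein output per sample
#'
#' For every protein and sample, the ratio of the sample's newly-synthesized
#' intensity to the mean intensity over all samples of that sample's condition
#' (the queried sample included, by default). Across the samples of one
#' condition these ratios average to exactly 1 for every protein.
#'
#' @param experiment A `tmt_experiment`-shaped data frame.
#' @param include_self Include the queried sample in the condition mean
#'   (default TRUE, the literal "average of all samples in a given
#'   condition"); FALSE uses the leave-one-out mean.
#' @return Data frame `protein_id, sample_id, condition, perturbation,
#'   relative_output, defined`; `defined` is FALSE where the condition mean is
#'   zero (ratio NA).
#' @export
relative_output <- function(experiment, include_self = TRUE) {
  key <- paste(experiment$protein_id, experiment$condition, sep = "\r")
  cond_sum <- tapply(experiment$intensity, key, sum)
  cond_n <- tapply(experiment$intensity, key, length)
  s <- as.numeric(cond_sum[key]); m <- as.numeric(cond_n[key])
  if (include_self) {
    denom <- s / m
  } else {
    if (any(m < 2)) stop("leave-one-out mean needs >= 2 samples per condition")
    denom <- (s - experiment$intensity) / (m - 1)
  }
  out <- experiment[, c("protein_id", "sample_id", "condition", "perturbation")]
  out$relative_output <- ifelse(denom > 0, experiment$intensity / denom,
                                NA_real_)
  out$defined <- denom > 0
  rownames(out) <- NULL
  out
}

#' Classify oxygen response of protein output
#'
#' Assigns each protein to one of three classes from the ratio
#' `r = hypoxic output / normoxic output`: Class III (hypoxia-enriched,
#' `r >= 1.15`, at least 15% increase), Class I (normoxia-enriched,
#' `r <= 0.85`, at least 15% decrease), Class II otherwise (oxygen-neutral).
#' Boundaries are inclusive.
#'
#' @param hypoxic_output,normoxic_output Positive numeric vectors.
#' @param lower,upper Class boundaries (defaults 0.85 and 1.15).
#' @return Character vector of class labels `"I"`, `"II"`, `"III"`.
#' @export
classify_oxygen_response <- function(hypoxic_output, normoxic_output,
                                     lower = 0.85, upper = 1.15) {
  if (any(!is.finite(hypoxic_output)) || any(hypoxic_output <= 0) ||
      any(!is.finite(normoxic_output)) || any(normoxic_output <= 0)) {
    stop("outputs must be positive and finite")
  }
  r <- hypoxic_output / normoxic_output
  ifelse(r >= upper, "III", ifelse(r <= lower, "I", "II"))
}

#' Call RBP dependency from relative output of a silenced sample
#'
#' A protein is dependent on an RBP if silencing the RBP changes the protein's
#' relative output by at least `threshold` (default 15%), multiplicatively and
#' inclusively: ratio `<= 1 - threshold` is `dependent_down` (the RBP promotes
#' the protein's synthesis), ratio `>= 1 + threshold` is `dependent_up` (the
#' RBP represses it), anything between is `none`.
#'
#' @param ratio Positive numeric vector of relative outputs in the silenced
#'   sample.
#' @param threshold Fold-difference threshold in (0, 1).
#' @return Character vector: `"dependent_down"`, `"dependent_up"`, `"none"`.
#' @export
call_dependency <- function(ratio, threshold = 0.15) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      is.na(threshold) || threshold <= 0 || threshold >= 1) {
    stop("`threshold` must be a single number in (0, 1)")
  }
  if (any(!is.finite(ratio)) || any(ratio <= 0)) {
    stop("`ratio` must be positive and finite")
  }
  ifelse(ratio <= 1 - threshold, "dependent_down",
         ifelse(ratio >= 1 + threshold, "dependent_up", "none"))
}

#' Chi-square test of class composition against a background
#'
#' Pearson chi-square of observed subset class counts against expected counts
#' derived from background class proportions, as used to ask whether the
#' proteins downregulated by silencing one RBP are enriched for a particular
#' oxygen-response class relative to overall translatome remodeling. Classes
#' with zero background count carry no expectation: they are dropped from the
#' test (their observed counts excluded) and reported.
#'
#' @param subset_counts Named vector of observed class counts (total > 0).
#' @param background_counts Named vector of background class counts over the
#'   same classes.
#' @return An object of class `htest` with `statistic` (X-squared),
#'   `parameter` (df = number of nonzero background classes - 1), `p.value`,
#'   `observed` and `expected`; `dropped_classes` names any zero-background
#'   classes removed.
#' @export
composition_test <- function(subset_counts, background_counts) {
  if (is.null(names(subset_counts)) || is.null(names(background_counts))) {
    stop("counts must be named by class")
  }
  classes <- names(background_counts)
  obs <- stats::setNames(rep(0, length(classes)), classes)
  obs[names(subset_counts)] <- subset_counts
  dropped <- classes[background_counts == 0]
  keep <- background_counts > 0
  obs <- obs[keep]
  bg <- background_counts[keep]
  n <- sum(obs)
  if (n <= 0) stop("subset total must be positive")
  if (length(bg) < 2) stop("need at least two classes with background counts")
  expected <- n * bg / sum(bg)
  stat <- sum((obs - expected)^2 / expected)
  df <- length(bg) - 1
  structure(
    list(statistic = c("X-squared" = stat),
         parameter = c(df = df),
         p.value = stats::pchisq(stat, df, lower.tail = FALSE),
         method = "Pearson chi-square against background proportions",
         data.name = deparse(substitute(subset_counts)),
         observed = obs, expected = expected,
         dropped_classes = dropped),
    class = "htest"
  )
}

#' Full translatome classification from a TMT pulse-SILAC experiment
#'
#' Runs the whole protein-output analysis: optional total-intensity
#' normalization, relative output per sample, oxygen-response class per
#' protein (from the NS samples of each condition), RBP dependency calls (from
#' each silenced sample's relative output in `dependency_condition`), and a
#' per-RBP chi-square comparing the class composition of its dependent_down
#' targets with the overall remodeling, with Benjamini-Hochberg adjusted
#' p-values reported alongside the raw ones.
#'
#' @param experiment A `tmt_experiment`-shaped data frame.
#' @param threshold Dependency fold threshold (default 0.15).
#' @param normalize `"none"` (default) or `"total"`.
#' @param include_self Passed to [relative_output()].
#' @param dependency_condition Condition in which dependency is called
#'   (default `"hypoxia"`).
#' @return A list of class `translatome_result`: `classes` (protein, output
#'   ratio, oxygen class), `output` (relative outputs), `dependencies`
#'   (protein x RBP calls), `portfolios` (dependent_down ids per RBP), and
#'   `rbp_tests` (chi-square statistic, raw and BH-adjusted p per RBP).
#' @export
classify_translatome <- function(experiment, threshold = 0.15,
                                 normalize = c("none", "total"),
                                 include_self = TRUE,
                                 dependency_condition = "hypoxia") {
  normalize <- match.arg(normalize)
  if (normalize == "total") experiment <- tmt_total_normalize(experiment)

  ns <- experiment[experiment$perturbation == "NS", , drop = FALSE]
  if (!nrow(ns)) stop("experiment has no NS samples")
  ns_mean <- tapply(ns$intensity,
                    list(protein = ns$protein_id, condition = ns$condition),
                    mean)
  if (!all(c("normoxia", "hypoxia") %in% colnames(ns_mean))) {
    stop("oxygen classification needs NS samples in both conditions")
  }
  classes <- data.frame(
    protein_id = rownames(ns_mean),
    output_ratio = ns_mean[, "hypoxia"] / ns_mean[, "normoxia"],
    stringsAsFactors = FALSE
  )
  classes$oxygen_class <- classify_oxygen_response(ns_mean[, "hypoxia"],
                                                   ns_mean[, "normoxia"])
  rownames(classes) <- NULL

  rel <- relative_output(experiment, include_self = include_self)
  dep <- rel[rel$perturbation != "NS" &
               rel$condition == dependency_condition, , drop = FALSE]
  portfolios <- list()
  if (nrow(dep)) {
    dep$call <- "none"
    ok <- dep$defined & !is.na(dep$relative_output) & dep$relative_output > 0
    dep$call[ok] <- call_dependency(dep$relative_output[ok], threshold)
    dep <- dep[, c("protein_id", "perturbation", "relative_output", "call")]
    names(dep)[2] <- "rbp"
    portfolios <- split(dep$protein_id[dep$call == "dependent_down"],
                        dep$rbp[dep$call == "dependent_down"])
    portfolios <- lapply(portfolios, sort)
  } else {
    dep <- data.frame(protein_id = character(0), rbp = character(0),
                      relative_output = numeric(0), call = character(0))
  }

  background <- table(factor(classes$oxygen_class, c("I", "II", "III")))
  background <- stats::setNames(as.numeric(background), names(background))
  rbps <- sort(unique(dep$rbp))
  rbp_tests <- NULL
  if (length(rbps)) {
    rows <- lapply(rbps, function(r) {
      tgt <- portfolios[[r]]
      if (is.null(tgt) || !length(tgt)) {
        return(data.frame(rbp = r, n_targets = 0L, statistic = NA_real_,
                          df = NA_integer_, p.value = NA_real_))
      }
      cls <- classes$oxygen_class[match(tgt, classes$protein_id)]
      sub <- table(factor(cls, c("I", "II", "III")))
      ht <- composition_test(stats::setNames(as.numeric(sub), names(sub)),
                             background)
      data.frame(rbp = r, n_targets = length(tgt),
                 statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p.value = ht$p.value)
    })
    rbp_tests <- do.call(rbind, rows)
    rbp_tests$p.adjust_bh <- stats::p.adjust(rbp_tests$p.value, "BH")
  }

  structure(list(classes = classes, output = rel, dependencies = dep,
                 portfolios = portfolios, rbp_tests = rbp_tests,
                 threshold = threshold,
                 dependency_condition = dependency_condition),
            class = "translatome_result")
}

#' @export
print.translatome_result <- function(x, ...) {
  tab <- table(factor(x$classes$oxygen_class, c("I", "II", "III")))
  cat("<translatome_result> ", nrow(x$classes), " proteins classified: ",
      paste(names(tab), tab, sep = "=", collapse = " "), "\n", sep = "")
  if (length(x$portfolios)) {
    cat("  dependent_down targets (threshold ", x$threshold, ", ",
        x$dependency_condition, "): ",
        paste(names(x$portfolios), lengths(x$portfolios),
              sep = "=", collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

#' Planted-effect miss set under TMT ratio compression
#'
#' Under power-law ratio compression a true ratio `r` is observed as `r^kappa`
#' and crosses a classification boundary only if `r` itself crosses the
#' boundary raised to `1/kappa`. The predicted miss set of the 15% rule is
#' therefore `{r : boundary^(1/kappa)-interior but not boundary-interior}`.
#'
#' @param r True ratios.
#' @param kappa Compression exponent in (0, 1].
#' @param lower,upper Decision boundaries (defaults 0.85, 1.15).
#' @return Logical vector: TRUE where the planted effect is called at
#'   `kappa = 1` but missed at the given `kappa`.
#' @export
compression_miss <- function(r, kappa, lower = 0.85, upper = 1.15) {
  called_true <- r <= lower | r >= upper
  called_obs <- r^kappa <= lower | r^kappa >= upper
  called_true & !called_obs
}
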