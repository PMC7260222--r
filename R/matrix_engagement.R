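# MATRIX readout layer: per-protein translational-engagement ratios from
# fraction-level protein abundances, and hypoxic activation ranking.

#' Keep only light-channel SILAC signals
#'
#' Heavy-label signals mark proteins synthesized during the pulse and are
#' excluded so engagement readouts reflect the abundance of pre-existing
#' machinery components. Proteins with no light signal in any fraction are
#' dropped; their ids are attached as the `"dropped"` attribute and reported
#' via a message.
#'
#' @param table A `protein_fraction_table`-shaped data frame with columns
#'   `protein_id, fraction_id, condition, channel, abundance`.
#' @return The light-channel rows, same class; attribute `dropped` lists
#'   proteins removed for lacking light signal.
#' @export
filter_silac <- function(table) {
  if (!"channel" %in% names(table)) {
    stop("table has no `channel` column; SILAC channel annotation is required")
  }
  all_ids <- unique(table$protein_id)
  light <- table[table$channel == "light", , drop = FALSE]
  sums <- tapply(light$abundance, light$protein_id, sum)
  keep <- names(sums)[sums > 0]
  dropped <- setdiff(all_ids, keep)
  out <- light[light$protein_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  if (length(dropped)) {
    message("filter_silac: dropped ", length(dropped),
            " protein(s) with no light-channel signal")
  }
  attr(out, "dropped") <- dropped
  class(out) <- unique(c("protein_fraction_table", class(out)))
  out
}

#' Per-protein translational engagement ratios
#'
#' Aggregates light-channel abundances over the fractions of each compartment
#' and forms the three engagement readouts: polysome/free (`pf_ratio`, the
#' primary readout of translational involvement), polysome/monosome
#' (`pm_ratio`, the secondary readout, less sensitive to monosome-associated
#' decay factors), and monosome/free (`mf_ratio`, an initiation proxy). A zero
#' compartment denominator leaves the ratio undefined (NA) with its
#' `*_defined` flag FALSE; no pseudocount is applied.
#'
#' @param table A light-only `protein_fraction_table` (run [filter_silac()]
#'   first if heavy rows are present).
#' @param scheme A `fraction_scheme` covering every fraction in the table.
#' @param condition Condition to evaluate; default uses all rows (the table
#'   must then be single-condition).
#' @param aggregate `"sum"` (default; fractions are equal-volume) or `"mean"`.
#' @return Data frame of engagement records: `protein_id, condition,
#'   pf_ratio, pm_ratio, mf_ratio, pf_defined, pm_defined, mf_defined`.
#' @export
engagement_ratios <- function(table, scheme, condition = NULL,
                              aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(scheme, "fraction_scheme"))
  if ("channel" %in% names(table) && any(table$channel != "light")) {
    stop("table contains non-light channels; run filter_silac() first")
  }
  if (!is.null(condition)) {
    table <- table[table$condition == condition, , drop = FALSE]
    if (!nrow(table)) stop("no rows for condition ", condition)
  } else {
    conds <- unique(table$condition)
    if (length(conds) > 1) {
      stop("table has multiple conditions; pass `condition`")
    }
    condition <- conds
  }
  assert_fractions_known(scheme, table$fraction_id)
  if (any(table$abundance < 0)) stop("abundances must be non-negative")

  comp <- scheme$compartment[table$fraction_id]
  agg_fun <- if (aggregate == "sum") sum else mean
  sums <- tapply(table$abundance,
                 list(protein = table$protein_id, compartment = comp),
                 agg_fun, default = 0)
  for (cmp in .COMPARTMENTS) {
    if (!cmp %in% colnames(sums)) {
      sums <- cbind(sums, stats::setNames(
        matrix(0, nrow(sums), 1, dimnames = list(NULL, cmp)), cmp))
    }
  }
  free <- sums[, "free"]; mono <- sums[, "monosome"]; poly <- sums[, "polysome"]
  ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  out <- data.frame(
    protein_id = rownames(sums),
    condition = condition,
    pf_ratio = ratio(poly, free),
    pm_ratio = ratio(poly, mono),
    mf_ratio = ratio(mono, free),
    pf_defined = free > 0,
    pm_defined = mono > 0,
    mf_defined = free > 0,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Rank proteins by hypoxic activation of translational engagement
#'
#' Scores each protein by the log2 ratio of its hypoxic to normoxic
#' polysome/free engagement (`primary_score`), with the polysome/monosome
#' log-ratio as `secondary_score`. Proteins are ranked descending by primary
#' score (rank 1 = most activated), ties broken by secondary score descending,
#' then by protein id. Proteins whose primary ratio is undefined or zero in
#' either condition cannot be scored; they are excluded and reported in the
#' `"excluded"` attribute.
#'
#' @param normoxia,hypoxia Engagement-record data frames from
#'   [engagement_ratios()] for the two conditions, covering a shared protein
#'   set.
#' @return Data frame `protein_id, primary_score, secondary_score, rank`
#'   sorted by rank, with attribute `excluded` (data frame of protein id and
#'   reason).
#' @export
activation_ranking <- function(normoxia, hypoxia) {
  shared <- intersect(normoxia$protein_id, hypoxia$protein_id)
  if (!length(shared)) stop("no shared proteins between conditions")
  n <- normoxia[match(shared, normoxia$protein_id), ]
  h <- hypoxia[match(shared, hypoxia$protein_id), ]
  ok <- n$pf_defined & h$pf_defined &
    !is.na(n$pf_ratio) & !is.na(h$pf_ratio) &
    n$pf_ratio > 0 & h$pf_ratio > 0
  excluded <- data.frame(
    protein_id = shared[!ok],
    reason = ifelse(!n$pf_defined[!ok] | !h$pf_defined[!ok],
                    "undefined polysome/free ratio",
                    "zero polysome/free ratio"),
    stringsAsFactors = FALSE
  )
  primary <- log2(h$pf_ratio[ok] / n$pf_ratio[ok])
  sec_ok <- h$pm_defined[ok] & n$pm_defined[ok] &
    !is.na(h$pm_ratio[ok]) & !is.na(n$pm_ratio[ok]) &
    h$pm_ratio[ok] > 0 & n$pm_ratio[ok] > 0
  secondary <- rep(NA_real_, sum(ok))
  secondary[sec_ok] <- log2(h$pm_ratio[ok][sec_ok] / n$pm_ratio[ok][sec_ok])
  out <- data.frame(protein_id = shared[ok],
                    primary_score = primary,
                    secondary_score = secondary,
                    stringsAsFactors = FALSE)
  ord <- order(-out$primary_score,
               -ifelse(is.na(out$secondary_score), -Inf, out$secondary_score),
               out$protein_id)
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}
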