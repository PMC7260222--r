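# Set-level reporting: per-RBP target portfolios, union coverage of a protein
# universe, exclusive (UpSet-style) intersections, and annotation overlap.

#' Exclusive intersection counts of a set family
#'
#' Assigns every element of the union to exactly one membership pattern (the
#' full combination of sets containing it) and counts elements per pattern,
#' the bookkeeping behind UpSet plots. All `2^k - 1` patterns are reported,
#' zeros included; counts sum to the union size.
#'
#' @param sets Named list of character vectors (at most 10 sets).
#' @return Data frame `pattern` (set names joined by `"&"`), `degree`
#'   (number of sets in the pattern), `count`.
#' @export
exclusive_intersections <- function(sets) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("`sets` must be a fully named list")
  }
  k <- length(sets)
  if (k > 10) {
    stop("more than 10 sets (", k, "): exclusive patterns grow as 2^k; ",
         "restrict to the sets of interest")
  }
  sets <- lapply(sets, unique)
  elements <- unique(unlist(sets, use.names = FALSE))
  membership <- vapply(sets, function(s) elements %in% s,
                       logical(length(elements)))
  if (length(elements) == 1) membership <- matrix(membership, nrow = 1)
  pattern_of <- apply(membership, 1, function(m) {
    paste(names(sets)[m], collapse = "&")
  })
  combos <- unlist(lapply(seq_len(k), function(d) {
    utils::combn(names(sets), d, paste, collapse = "&", simplify = FALSE)
  }))
  counts <- table(factor(pattern_of, levels = combos))
  data.frame(pattern = combos,
             degree = lengths(strsplit(combos, "&", fixed = TRUE)),
             count = as.integer(counts),
             stringsAsFactors = FALSE)
}

#' Union coverage of a universe by RBP target portfolios
#'
#' Fraction of a protein universe (e.g., the hypoxia-inducible Class III
#' population) covered by the union of per-RBP dependent-target portfolios,
#' with per-RBP counts/fractions and exclusive intersection patterns.
#' Portfolio members outside the universe are dropped (and counted in the
#' `n_outside_universe` field) rather than raising an error, since annotation
#' and target lists may exceed the detected proteome.
#'
#' @param universe Character vector, the reference population (non-empty).
#' @param portfolios Named list of character vectors (target ids per RBP).
#' @return A list of class `coverage_report`: `universe_size`, `union_size`,
#'   `union_fraction`, `per_rbp` (data frame rbp/count/fraction),
#'   `exclusive_patterns`, `n_outside_universe`.
#' @export
union_coverage <- function(universe, portfolios) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("`universe` must be non-empty")
  if (is.null(names(portfolios))) stop("`portfolios` must be named")
  raw_n <- sum(lengths(lapply(portfolios, unique)))
  portfolios <- lapply(portfolios, function(s) intersect(unique(s), universe))
  n_outside <- raw_n - sum(lengths(portfolios))
  if (n_outside > 0) {
    message("union_coverage: dropped ", n_outside,
            " portfolio member(s) outside the universe")
  }
  un <- unique(unlist(portfolios, use.names = FALSE))
  per_rbp <- data.frame(
    rbp = names(portfolios),
    count = vapply(portfolios, length, integer(1)),
    fraction = vapply(portfolios, length, integer(1)) / length(universe),
    stringsAsFactors = FALSE
  )
  rownames(per_rbp) <- NULL
  patterns <- if (length(portfolios)) exclusive_intersections(portfolios)
              else NULL
  structure(
    list(universe_size = length(universe),
         union_size = length(un),
         union_fraction = length(un) / length(universe),
         per_rbp = per_rbp,
         exclusive_patterns = patterns,
         n_outside_universe = n_outside),
    class = "coverage_report"
  )
}

#' @export
print.coverage_report <- function(x, ...) {
  cat("<coverage_report> union ", x$union_size, "/", x$universe_size,
      " = ", sprintf("%.1f%%", 100 * x$union_fraction), "\n", sep = "")
  for (i in seq_len(nrow(x$per_rbp))) {
    cat(sprintf("  %-12s %5d (%.1f%%)\n", x$per_rbp$rbp[i],
                x$per_rbp$count[i], 100 * x$per_rbp$fraction[i]))
  }
  invisible(x)
}

#' Overlap between a target set and an annotation set
#'
#' Counts the intersection of a target set (e.g., RBP-dependent Class III
#' proteins) with a user-supplied annotation (e.g., documented HIF
#' transcriptional targets), reporting the fraction of the annotation covered
#' and the fraction of targets annotated. If a universe is supplied, both sets
#' are first restricted to it (dropped counts reported).
#'
#' @param targets Character vector of target ids.
#' @param annotation Non-empty character vector of annotated ids.
#' @param universe Optional character vector to restrict both sets.
#' @return List: `n_overlap`, `n_targets`, `n_annotation`,
#'   `fraction_annotation_covered`, `fraction_targets_annotated`,
#'   `n_dropped_targets`, `n_dropped_annotation`.
#' @export
annotate_overlap <- function(targets, annotation, universe = NULL) {
  annotation <- unique(as.character(annotation))
  if (!length(annotation)) stop("`annotation` must be non-empty")
  targets <- unique(as.character(targets))
  n_dt <- 0L; n_da <- 0L
  if (!is.null(universe)) {
    universe <- unique(as.character(universe))
    n_dt <- length(setdiff(targets, universe))
    n_da <- length(setdiff(annotation, universe))
    targets <- intersect(targets, universe)
    annotation <- intersect(annotation, universe)
    if (!length(annotation)) stop("annotation is empty after universe restriction")
  }
  ov <- intersect(targets, annotation)
  list(n_overlap = length(ov),
       n_targets = length(targets),
       n_annotation = length(annotation),
       fraction_annotation_covered = length(ov) / length(annotation),
       fraction_targets_annotated =
         if (length(targets)) length(ov) / length(targets) else NA_real_,
       n_dropped_targets = n_dt,
       n_dropped_annotation = n_da)
}
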