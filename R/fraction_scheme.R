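# Gradient fraction schemes: ordered sucrose-gradient fractions with a
# compartment assignment (free / monosome / polysome) and an optional
# ribosome-count annotation on polysome fractions.

.COMPARTMENTS <- c("free", "monosome", "polysome")

#' Define a gradient fraction scheme
#'
#' A fraction scheme describes the ordered fractions collected from a sucrose
#' density gradient and assigns each to one of three compartments:
#' `free` (ribosome-unbound material), `monosome` (40S/60S/80S region), or
#' `polysome` (multi-ribosome region). Polysome fractions may carry a
#' ribosome-count annotation used by the fraction RNA-seq simulator and by
#' heavy-polysome summaries.
#'
#' @param fraction_ids Character vector of fraction identifiers, in gradient
#'   order (top of gradient first).
#' @param compartment Character vector, same length, each element one of
#'   `"free"`, `"monosome"`, `"polysome"`.
#' @param ribosome_count Optional integer vector (NA where not annotated)
#'   giving the nominal ribosome count of each fraction. Where present it must
#'   be non-decreasing along gradient order.
#' @return An object of class `fraction_scheme`.
#' @examples
#' sc <- fraction_scheme(c("F1", "F2", "F3"),
#'                       c("free", "monosome", "polysome"))
#' compartment_fractions(sc, "polysome")
#' @export
fraction_scheme <- function(fraction_ids, compartment, ribosome_count = NULL) {
  fraction_ids <- as.character(fraction_ids)
  compartment <- as.character(compartment)
  if (length(fraction_ids) != length(compartment)) {
    stop("`fraction_ids` and `compartment` must have the same length")
  }
  if (anyDuplicated(fraction_ids)) {
    stop("duplicated fraction identifiers: ",
         paste(unique(fraction_ids[duplicated(fraction_ids)]), collapse = ", "))
  }
  bad <- setdiff(unique(compartment), .COMPARTMENTS)
  if (length(bad)) {
    stop("unknown compartment(s): ", paste(bad, collapse = ", "),
         " (expected free/monosome/polysome)")
  }
  missing_comp <- setdiff(.COMPARTMENTS, unique(compartment))
  if (length(missing_comp)) {
    stop("scheme must contain at least one fraction per compartment; missing: ",
         paste(missing_comp, collapse = ", "))
  }
  if (is.null(ribosome_count)) {
    ribosome_count <- rep(NA_integer_, length(fraction_ids))
  } else {
    ribosome_count <- as.integer(ribosome_count)
    if (length(ribosome_count) != length(fraction_ids)) {
      stop("`ribosome_count` must match `fraction_ids` in length")
    }
    if (any(ribosome_count < 0, na.rm = TRUE)) {
      stop("ribosome counts must be non-negative")
    }
    ann <- ribosome_count[!is.na(ribosome_count)]
    if (length(ann) > 1 && any(diff(ann) < 0)) {
      stop("ribosome counts must be non-decreasing along gradient order")
    }
  }
  structure(
    list(fraction_ids = fraction_ids,
         compartment = stats::setNames(compartment, fraction_ids),
         ribosome_count = stats::setNames(ribosome_count, fraction_ids)),
    class = "fraction_scheme"
  )
}

#' Default 12-fraction gradient scheme
#'
#' Twelve equal-volume fractions from a 10-50% sucrose gradient: 2 free,
#' 3 monosome (40S/60S/80S pooled), and 7 polysome fractions annotated with
#' ribosome counts 2..8. The heavy-polysome region (>= 5 ribosomes) therefore
#' begins at fraction `P5`. The compartment boundaries are a package
#' convention: gradients resolve compartments, not exact fraction indices.
#'
#' @return A `fraction_scheme`.
#' @export
default_fraction_scheme <- function() {
  fraction_scheme(
    fraction_ids = c("FR1", "FR2", "M1", "M2", "M3",
                     "P2", "P3", "P4", "P5", "P6", "P7", "P8"),
    compartment = c(rep("free", 2), rep("monosome", 3), rep("polysome", 7)),
    ribosome_count = c(rep(NA_integer_, 5), 2:8)
  )
}

#' Fractions belonging to a compartment
#' @param scheme A `fraction_scheme`.
#' @param compartment One of `"free"`, `"monosome"`, `"polysome"`.
#' @return Character vector of fraction ids, in gradient order.
#' @export
compartment_fractions <- function(scheme, compartment) {
  stopifnot(inherits(scheme, "fraction_scheme"))
  compartment <- match.arg(compartment, .COMPARTMENTS)
  scheme$fraction_ids[scheme$compartment[scheme$fraction_ids] == compartment]
}

#' @export
print.fraction_scheme <- function(x, ...) {
  cat("<fraction_scheme> ", length(x$fraction_ids), " fractions (",
      sum(x$compartment == "free"), " free / ",
      sum(x$compartment == "monosome"), " monosome / ",
      sum(x$compartment == "polysome"), " polysome)\n", sep = "")
  rc <- x$ribosome_count
  ann <- !is.na(rc)
  if (any(ann)) {
    cat("  ribosome counts: ",
        paste0(names(rc)[ann], "=", rc[ann], collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

# Maximum annotated ribosome count (tail-lumping bound for load simulation).
max_ribosome_count <- function(scheme) {
  rc <- scheme$ribosome_count
  if (all(is.na(rc))) return(NA_integer_)
  max(rc, na.rm = TRUE)
}

# Check that every fraction id in `ids` is covered by the scheme; error names
# the offending fraction(s).
assert_fractions_known <- function(scheme, ids) {
  unknown <- setdiff(unique(as.character(ids)), scheme$fraction_ids)
  if (length(unknown)) {
    stop("fraction(s) not in scheme: ", paste(unknown, collapse = ", "))
  }
  invisible(TRUE)
}
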