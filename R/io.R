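# Plain-text I/O: TSV tables (full-precision round trip), fraction-scheme and
# key-value config files, set files, and dataset emission with a manifest.

# Write a data frame as TSV with numerics at full (17 significant digit)
# precision so write/read round trips reproduce values exactly.
write_tsv <- function(df, path) {
  out <- as.data.frame(df)
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, numeric_cols = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  for (col in intersect(numeric_cols, names(df))) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df
}

#' Read a fraction-level protein abundance table
#'
#' Expects TSV columns `protein_id, fraction_id, condition, channel,
#' abundance`.
#' @param path File path.
#' @return A `protein_fraction_table` data frame.
#' @export
read_protein_fraction_table <- function(path) {
  df <- read_tsv(path, numeric_cols = "abundance")
  need <- c("protein_id", "fraction_id", "condition", "channel", "abundance")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop(path, " lacks column(s): ", paste(miss, collapse = ", "))
  if (any(df$abundance < 0)) stop("abundances must be non-negative")
  class(df) <- c("protein_fraction_table", "data.frame")
  df
}

#' Read a TMT channel-intensity table
#'
#' Expects TSV columns `protein_id, sample_id, condition, perturbation,
#' intensity`.
#' @param path File path.
#' @return A `tmt_experiment` data frame.
#' @export
read_tmt_table <- function(path) {
  df <- read_tsv(path, numeric_cols = "intensity")
  need <- c("protein_id", "sample_id", "condition", "perturbation", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop(path, " lacks column(s): ", paste(miss, collapse = ", "))
  if (any(df$intensity < 0)) stop("intensities must be non-negative")
  class(df) <- c("tmt_experiment", "data.frame")
  df
}

#' Read a fraction-level FPKM table
#'
#' Expects TSV columns `gene_id, sample_id, fraction_id, fpkm`.
#' @param path File path.
#' @return A `fraction_fpkm_table` data frame.
#' @export
read_fpkm_table <- function(path) {
  df <- read_tsv(path, numeric_cols = "fpkm")
  need <- c("gene_id", "sample_id", "fraction_id", "fpkm")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop(path, " lacks column(s): ", paste(miss, collapse = ", "))
  if (any(df$fpkm < 0)) stop("FPKM values must be non-negative")
  class(df) <- c("fraction_fpkm_table", "data.frame")
  df
}

#' Read identifier set files
#'
#' Each file is one set: a header line carrying the set name, then one
#' identifier per line.
#' @param paths Character vector of file paths.
#' @return Named list of character vectors.
#' @export
read_set_files <- function(paths) {
  sets <- list()
  for (p in paths) {
    if (!file.exists(p)) stop("file not found: ", p)
    lines <- readLines(p)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("empty set file: ", p)
    sets[[trimws(lines[1])]] <- trimws(lines[-1])
  }
  sets
}

#' Write a fraction scheme to a key-value text file
#'
#' Format: one `fraction_id: compartment` line per fraction (gradient order),
#' with an optional trailing ribosome count, e.g. `P5: polysome 5`.
#' @param scheme A `fraction_scheme`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fraction_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "fraction_scheme"))
  rc <- scheme$ribosome_count[scheme$fraction_ids]
  lines <- paste0(scheme$fraction_ids, ": ",
                  scheme$compartment[scheme$fraction_ids],
                  ifelse(is.na(rc), "", paste0(" ", rc)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a fraction scheme from a key-value text file
#' @param path File written by [write_fraction_scheme()] (or by hand, same
#'   format; `#` comment lines and blanks are ignored).
#' @return A `fraction_scheme`.
#' @export
read_fraction_scheme <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- regmatches(lines, regexec("^([^:]+):\\s*(\\S+)(\\s+(\\d+))?\\s*$",
                                     lines))
  bad <- lines[vapply(parts, length, integer(1)) == 0]
  if (length(bad)) stop("unparseable scheme line(s): ",
                        paste(bad, collapse = "; "))
  ids <- vapply(parts, `[`, character(1), 2)
  comp <- vapply(parts, `[`, character(1), 3)
  rc <- vapply(parts, `[`, character(1), 5)
  fraction_scheme(trimws(ids), comp,
                  ifelse(nzchar(rc) & !is.na(rc), suppressWarnings(as.integer(rc)),
                         NA_integer_))
}

#' Read a flat key-value configuration file
#'
#' One `key: value` pair per line; `#` comments and blank lines ignored.
#' Values that parse as numbers are returned numeric.
#' @param path File path.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^:]+):\\s*(.*)$", ln))[[1]]
    if (!length(m)) stop("unparseable config line: ", ln)
    key <- trimws(m[2]); val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Write a synthetic dataset to disk with a manifest
#'
#' Writes each table as TSV into `output_directory` and a `manifest.txt`
#' recording generation parameters and an MD5 checksum per file. Writing the
#' same tables again leaves the checksums unchanged, and reading the TSVs back
#' reproduces the numeric values exactly.
#'
#' @param tables Named list of data frames (names become `<name>.tsv`).
#' @param output_directory Existing, writable directory (an error names the
#'   path otherwise).
#' @param config Optional named list echoed into the manifest.
#' @param seed Optional seed echoed into the manifest.
#' @return Data frame `file, md5` (the manifest body), invisibly.
#' @export
emit_dataset <- function(tables, output_directory, config = NULL, seed = NULL) {
  if (!dir.exists(output_directory)) {
    stop("output directory does not exist: ", output_directory)
  }
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    stop("`tables` must be a fully named list")
  }
  files <- character(0)
  for (nm in names(tables)) {
    f <- file.path(output_directory, paste0(nm, ".tsv"))
    write_tsv(tables[[nm]], f)
    files <- c(files, f)
  }
  sums <- tools::md5sum(files)
  manifest <- data.frame(file = basename(files), md5 = unname(sums),
                         stringsAsFactors = FALSE)
  lines <- c("# ribofrac dataset manifest",
             paste0("generated: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  if (!is.null(seed)) lines <- c(lines, paste0("seed: ", seed))
  for (key in names(config)) {
    lines <- c(lines, paste0("config.", key, ": ",
                             paste(config[[key]], collapse = ",")))
  }
  lines <- c(lines, paste0("md5 ", manifest$md5, "  ", manifest$file))
  writeLines(lines, file.path(output_directory, "manifest.txt"))
  invisible(manifest)
}
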