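# Delimited-table import/export for externally quantified data: per-position
# peak-area tables (e.g. exported from a trace viewer or from a supplementary
# calculation workbook re-saved as CSV), Bioanalyzer band tables for the CAPS
# assay, calibration series, and the results TSV.

sniff_delimiter <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (!length(first))
    stop_sangeredit(paste0("empty file: ", path), "sangeredit_format_error")
  counts <- c("," = lengths(regmatches(first, gregexpr(",", first, fixed = TRUE))),
              "\t" = lengths(regmatches(first, gregexpr("\t", first, fixed = TRUE))),
              ";" = lengths(regmatches(first, gregexpr(";", first, fixed = TRUE))))
  if (all(counts == 0))
    stop_sangeredit(paste0("no supported delimiter (comma/tab/semicolon) in header of ", path),
                    "sangeredit_format_error")
  names(counts)[which.max(counts)]
}

read_delim_strict <- function(path, required, numeric_cols) {
  sep <- sniff_delimiter(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          strip.white = TRUE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_sangeredit(paste0(path, ": missing required column(s): ",
                           paste(missing, collapse = ", ")),
                    "sangeredit_schema_error")
  for (cc in intersect(numeric_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (anyNA(v) && !anyNA(df[[cc]]))
      stop_sangeredit(paste0(path, ": column ", cc, " is not numeric"),
                      "sangeredit_value_error")
    df[[cc]] <- v
  }
  df
}

#' Read a per-position four-channel peak-area table
#'
#' Ingests externally quantified peak areas (one row per called base) such as
#' tables exported from trace-viewer software or from a supplementary
#' calculation workbook re-saved as delimited text. The delimiter is
#' auto-detected among comma, tab and semicolon. Column names are remappable
#' via `columns`, so differently headed worksheets can be imported without
#' editing the file.
#'
#' Two layouts are accepted: raw areas (columns `position`, `base`, `area_A`,
#' `area_C`, `area_G`, `area_T`) or precomputed per-position editing ratios
#' (columns `position`, `base`, `editing`); the latter skips peak
#' integration downstream.
#'
#' @param path Path to a delimited text file with a header row.
#' @param columns Named character vector mapping the canonical column names
#'   to the names used in the file, e.g. `c(position = "Pos", area_A = "A")`.
#' @return A `peak_quant_table` data frame (raw layout) or an
#'   `editing_ratio_table` data frame (ratio layout), ordered by position.
#' @export
read_peak_table <- function(path, columns = NULL) {
  sep <- sniff_delimiter(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          strip.white = TRUE)
  if (!is.null(columns))
    for (canon in names(columns)) {
      if (!columns[[canon]] %in% names(df))
        stop_sangeredit(paste0(path, ": mapped column '", columns[[canon]],
                               "' not found"), "sangeredit_schema_error")
      names(df)[names(df) == columns[[canon]]] <- canon
    }

  area_cols <- paste0("area_", CHANNEL_BASES)
  is_ratio <- "editing" %in% names(df) && !all(area_cols %in% names(df))
  required <- c("position", "base", if (is_ratio) "editing" else area_cols)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_sangeredit(paste0(path, ": missing required column(s): ",
                           paste(missing, collapse = ", ")),
                    "sangeredit_schema_error")
  num_cols <- setdiff(required, "base")
  for (cc in num_cols) df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
  if (anyNA(df$position) || any(df$position != round(df$position)))
    stop_sangeredit(paste0(path, ": positions must be integers"),
                    "sangeredit_value_error")
  if (is.unsorted(df$position, strictly = TRUE))
    stop_sangeredit(paste0(path, ": positions must be strictly increasing"),
                    "sangeredit_value_error")
  if (is_ratio) {
    bad <- which(!is.na(df$editing) & (df$editing < 0 | df$editing > 1))
    if (length(bad))
      stop_sangeredit(paste0(path, ": editing ratio outside [0,1] at row ", bad[1]),
                      "sangeredit_value_error")
    out <- df[, c("position", "base", "editing")]
    class(out) <- c("editing_ratio_table", "data.frame")
    return(out)
  }
  for (cc in area_cols) {
    bad <- which(is.na(df[[cc]]) | df[[cc]] < 0)
    if (length(bad))
      stop_sangeredit(paste0(path, ": negative or missing ", cc, " at row ", bad[1]),
                      "sangeredit_value_error")
  }
  out <- df[, c("position", "base", area_cols)]
  out$base <- toupper(out$base)
  class(out) <- c("peak_quant_table", "data.frame")
  out
}

#' Write a peak-area table as delimited text
#'
#' @param peaks A `peak_quant_table` (from [integrate_called_peaks()] or
#'   [read_peak_table()]).
#' @param path Output path; extension `.csv` writes comma-separated,
#'   anything else tab-separated.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(peaks, path) {
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  utils::write.table(as.data.frame(peaks), path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a reference amplicon sequence from FASTA
#'
#' @param path FASTA file with at least one record.
#' @param id Optional record id to select; by default the first record is
#'   used.
#' @return A character scalar (uppercase DNA sequence) with attribute `id`.
#' @export
read_reference <- function(path, id = NULL) {
  if (!file.exists(path) || file.info(path)$size == 0)
    stop_sangeredit(paste0("empty or missing FASTA: ", path),
                    "sangeredit_format_error")
  seqs <- Biostrings::readDNAStringSet(path)
  if (!length(seqs))
    stop_sangeredit(paste0("no records in FASTA: ", path),
                    "sangeredit_format_error")
  ids <- sub("\\s.*$", "", names(seqs))
  if (is.null(id)) {
    pick <- 1L
  } else {
    pick <- which(ids == id)
    if (!length(pick))
      stop_sangeredit(paste0("id '", id, "' not found in ", path),
                      "sangeredit_content_error")
    if (length(pick) > 1L)
      stop_sangeredit(paste0("id '", id, "' is duplicated in ", path),
                      "sangeredit_content_error")
  }
  out <- toupper(as.character(seqs[[pick]]))
  attr(out, "id") <- ids[pick]
  out
}

results_rep_cols <- function(df) grep("^raw_rep_", names(df), value = TRUE)

#' Write per-site significance results as TSV
#'
#' One row per candidate site with 1-based reference position, reference
#' base, each sample replicate's raw editing value, control mean, corrected
#' mean and SD, the two criterion flags and the final significance call.
#' Column order is fixed so downstream parsing is stable.
#'
#' @param results A `significance_result` data frame from
#'   [call_significant_sites()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  df <- as.data.frame(results)
  cols <- c("ref_position", "ref_base", results_rep_cols(df),
            "n_sample", "n_control", "evaluable", "raw_mean", "control_mean",
            "corrected_mean", "corrected_sd", "criterion1", "criterion2",
            "significant")
  df <- df[, cols, drop = FALSE]
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], signif, digits = 6)
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok)
    stop_sangeredit(paste0("cannot write results to ", path),
                    "sangeredit_io_error")
  invisible(path)
}

#' Read back a results TSV written by [write_results()]
#'
#' @param path Results TSV path.
#' @return A `significance_result` data frame.
#' @export
read_results <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  required <- c("ref_position", "ref_base", "raw_mean", "control_mean",
                "corrected_mean", "corrected_sd", "criterion1", "criterion2",
                "significant")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_sangeredit(paste0(path, ": missing required column(s): ",
                           paste(missing, collapse = ", ")),
                    "sangeredit_schema_error")
  for (cc in c("evaluable", "criterion1", "criterion2", "significant"))
    if (cc %in% names(df)) df[[cc]] <- as.logical(df[[cc]])
  class(df) <- c("significance_result", "data.frame")
  df
}

#' Read a Bioanalyzer-style band-quantity table
#'
#' Per-lane fragment sizes and quantities for the CAPS assay. Expected
#' columns: `lane_id`, `treatment` (`digested` or `undigested`), `length_nt`,
#' `quantity`, and optionally `unit` (`molar` or `mass`; mass quantities are
#' converted to molar scale by dividing by fragment length, since cleaved
#' fragments are shorter).
#'
#' @param path Delimited text file (comma/tab/semicolon auto-detected).
#' @return A `band_table` data frame with molar-scale `quantity`.
#' @export
read_band_table <- function(path) {
  df <- read_delim_strict(path,
                          required = c("lane_id", "treatment", "length_nt", "quantity"),
                          numeric_cols = c("length_nt", "quantity"))
  df$treatment <- tolower(df$treatment)
  bad <- setdiff(unique(df$treatment), c("digested", "undigested"))
  if (length(bad))
    stop_sangeredit(paste0(path, ": unknown treatment value(s): ",
                           paste(bad, collapse = ", ")),
                    "sangeredit_value_error")
  if (any(df$quantity < 0, na.rm = TRUE))
    stop_sangeredit(paste0(path, ": negative band quantity"),
                    "sangeredit_value_error")
  if (any(df$length_nt <= 0, na.rm = TRUE))
    stop_sangeredit(paste0(path, ": non-positive band length"),
                    "sangeredit_value_error")
  if ("unit" %in% names(df)) {
    u <- tolower(df$unit)
    bad <- setdiff(unique(u), c("molar", "mass"))
    if (length(bad))
      stop_sangeredit(paste0(path, ": unknown unit value(s): ",
                             paste(bad, collapse = ", ")),
                    "sangeredit_value_error")
    df$quantity <- ifelse(u == "mass", df$quantity / df$length_nt, df$quantity)
    df$unit <- NULL
  }
  class(df) <- c("band_table", "data.frame")
  df
}

#' Read a calibration series (expected vs measured fraction)
#'
#' @param path Delimited text file with columns `expected_fraction` and
#'   `measured_fraction`.
#' @return A `calibration_series` data frame.
#' @export
read_calibration_table <- function(path) {
  df <- read_delim_strict(path,
                          required = c("expected_fraction", "measured_fraction"),
                          numeric_cols = c("expected_fraction", "measured_fraction"))
  if (any(df$expected_fraction < 0 | df$expected_fraction > 1 |
          df$measured_fraction < 0 | df$measured_fraction > 1, na.rm = TRUE))
    stop_sangeredit(paste0(path, ": fractions must lie in [0,1]"),
                    "sangeredit_value_error")
  class(df) <- c("calibration_series", "data.frame")
  df
}
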