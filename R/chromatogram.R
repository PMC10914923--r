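#' @keywords internal
"_PACKAGE"

utils::globalVariables(c("ref_position", "percent", "status",
                         "measured_fraction", "expected_fraction"))

# Condition helpers: every user-facing error carries a subclass so callers
# (and the command-line wrapper) can map failure modes to exit codes.
stop_sangeredit <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "sangeredit_error", "error")))
}

CHANNEL_BASES <- c("A", "C", "G", "T")

#' Construct a four-channel Sanger chromatogram
#'
#' The in-memory representation of an electropherogram: four equal-length
#' fluorescence trace arrays (one per base), the basecalled sequence, and the
#' trace-array index of each called peak. Traces are stored in fixed A, C, G,
#' T column order regardless of the instrument's dye order; [read_ab1()]
#' permutes channels on import using the file's channel-order record.
#'
#' @param traces Numeric matrix, one row per trace sample, columns named
#'   `A`, `C`, `G`, `T` (any order; they are rearranged). Non-negative.
#' @param basecalls Character scalar or vector of IUPAC DNA letters
#'   (including ambiguity codes and `N`), one letter per called peak.
#' @param peak_locations Integer vector of 0-based trace-sample indices of
#'   the called peaks, strictly increasing, same length as `basecalls`.
#' @param sample_id Character scalar identifying the read.
#' @param quality Optional numeric per-basecall quality scores.
#' @param channel_order The dye order the traces were stored in on disk
#'   (provenance only; traces here are always A,C,G,T).
#'
#' @return An object of class `chromatogram`.
#' @export
chromatogram <- function(traces, basecalls, peak_locations,
                         sample_id = "trace", quality = NULL,
                         channel_order = CHANNEL_BASES) {
  traces <- as.matrix(traces)
  if (ncol(traces) != 4L || !setequal(colnames(traces), CHANNEL_BASES))
    stop_sangeredit("traces must have exactly the four columns A, C, G, T",
                    "sangeredit_content_error")
  traces <- traces[, CHANNEL_BASES, drop = FALSE]
  storage.mode(traces) <- "double"
  if (any(!is.finite(traces)) || any(traces < 0))
    stop_sangeredit("trace signals must be finite and non-negative",
                    "sangeredit_content_error")
  basecalls <- toupper(paste(basecalls, collapse = ""))
  calls <- strsplit(basecalls, "")[[1]]
  bad <- setdiff(unique(calls), names(Biostrings::IUPAC_CODE_MAP))
  if (length(bad))
    stop_sangeredit(paste0("basecalls contain non-IUPAC letters: ",
                           paste(bad, collapse = ",")),
                    "sangeredit_content_error")
  peak_locations <- as.integer(peak_locations)
  if (length(peak_locations) != length(calls))
    stop_sangeredit("basecalls and peak_locations lengths differ",
                    "sangeredit_content_error")
  if (length(peak_locations) &&
      (any(diff(peak_locations) <= 0L) ||
       min(peak_locations) < 0L || max(peak_locations) >= nrow(traces)))
    stop_sangeredit("peak_locations must be strictly increasing and within trace bounds",
                    "sangeredit_content_error")
  if (!is.null(quality) && length(quality) != length(calls))
    stop_sangeredit("quality must have one score per basecall",
                    "sangeredit_content_error")
  structure(
    list(sample_id = as.character(sample_id)[1],
         traces = traces,
         basecalls = basecalls,
         peak_locations = peak_locations,
         quality = quality,
         channel_order = channel_order),
    class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("<chromatogram> %s: %d basecalls, %d trace samples x 4 channels\n",
              x$sample_id, nchar(x$basecalls), nrow(x$traces)))
  invisible(x)
}

#' @export
length.chromatogram <- function(x) nchar(x$basecalls)

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Reverse-complement a chromatogram
#'
#' For reads sequenced with a reverse primer: reverses all traces and peak
#' locations and swaps complementary channels (A with T, C with G), so that
#' an A-to-G editing event read as T-to-C on the trace appears as A-to-G
#' after transformation.
#'
#' @param chrom A [chromatogram()].
#' @return A `chromatogram` on the opposite strand.
#' @export
reverse_complement_chromatogram <- function(chrom) {
  n <- nrow(chrom$traces)
  tr <- chrom$traces[n:1, c("T", "G", "C", "A"), drop = FALSE]
  colnames(tr) <- CHANNEL_BASES
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(chrom$basecalls)))
  chromatogram(tr, rc,
               rev((n - 1L) - chrom$peak_locations),
               sample_id = chrom$sample_id,
               quality = if (is.null(chrom$quality)) NULL else rev(chrom$quality),
               channel_order = chrom$channel_order)
}

# Two-base IUPAC code lookup used by the simulator's basecaller.
iupac_for_bases <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  map <- Biostrings::IUPAC_CODE_MAP
  hit <- names(map)[match(key, vapply(map, function(s)
    paste(sort(strsplit(s, "")[[1]]), collapse = ""), ""))]
  if (is.na(hit)) "N" else hit
}
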