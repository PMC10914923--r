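# End-to-end orchestration: quantify traces against a reference, assemble
# sample/control editing tables, apply the significance criteria, and render
# the editing-profile display (percent editing per candidate position along
# the amplicon, significant sites highlighted).

#' Quantify a set of chromatograms against a reference
#'
#' For each trace: integrate per-base peak areas and align the basecalls to
#' the reference. Failures are reported per input with its identifier.
#'
#' @param chroms List of [chromatogram()]s (or paths to AB1 files, which are
#'   read first).
#' @param reference Reference amplicon sequence (character, or path to a
#'   FASTA read via [read_reference()] if the string looks like a file).
#' @param baseline Baseline mode for [integrate_called_peaks()].
#' @param identity_floor Passed to [align_basecalls()].
#' @param orientation `"forward"` (default) or `"reverse"`; reverse reads
#'   are reverse-complemented before quantification.
#' @return A list with elements `peaks` (list of `peak_quant_table`s) and
#'   `maps` (list of `site_map`s), one per input.
#' @export
quantify_traces <- function(chroms, reference, baseline = "window_min",
                            identity_floor = 0.7,
                            orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  if (inherits(chroms, "chromatogram")) chroms <- list(chroms)
  chroms <- lapply(chroms, function(x) {
    if (is.character(x)) x <- read_ab1(x)
    if (orientation == "reverse") x <- reverse_complement_chromatogram(x)
    x
  })
  peaks <- vector("list", length(chroms))
  maps <- vector("list", length(chroms))
  for (i in seq_along(chroms)) {
    id <- chroms[[i]]$sample_id
    peaks[[i]] <- tryCatch(integrate_called_peaks(chroms[[i]], baseline),
                           sangeredit_error = function(e)
                             stop_sangeredit(paste0(id, ": ", conditionMessage(e)),
                                             class(e)[1]))
    maps[[i]] <- tryCatch(align_basecalls(chroms[[i]]$basecalls, reference,
                                          identity_floor),
                          sangeredit_error = function(e)
                            stop_sangeredit(paste0(id, ": ", conditionMessage(e)),
                                            class(e)[1]))
  }
  list(peaks = peaks, maps = maps,
       ids = vapply(chroms, function(x) x$sample_id, ""))
}

#' Attach reference positions to a quantified peak table
#'
#' Converts a call-indexed `peak_quant_table` into the external
#' reference-coordinate layout (`position`, `base`, `area_A` .. `area_T`)
#' using the read's site map; unaligned calls are dropped.
#'
#' @param peaks A `peak_quant_table` from [integrate_called_peaks()].
#' @param site_map A `site_map` from [align_basecalls()].
#' @return A `peak_quant_table` data frame in reference coordinates.
#' @export
annotate_positions <- function(peaks, site_map) {
  idx <- match(site_map$call_index, peaks$call_index)
  out <- data.frame(position = site_map$ref_position,
                    base = peaks$called_base[idx],
                    stringsAsFactors = FALSE)
  out[paste0("area_", CHANNEL_BASES)] <-
    as.data.frame(peaks)[idx, paste0("area_", CHANNEL_BASES)]
  out <- out[!is.na(idx), , drop = FALSE]
  class(out) <- c("peak_quant_table", "data.frame")
  out
}

#' Run the full editing-calling pipeline on chromatograms
#'
#' Quantifies sample and control traces, builds the editing tables at every
#' candidate substrate position of the reference, and applies the two
#' significance criteria.
#'
#' @param sample_chroms,control_chroms Lists of [chromatogram()]s (or AB1
#'   paths).
#' @param reference Reference amplicon sequence.
#' @param edit_mode `"A_to_G"` or `"C_to_T"`.
#' @param min_replicates,strict_criterion2 Passed to
#'   [call_significant_sites()].
#' @param min_total_area Passed to [editing_ratio()].
#' @param baseline,identity_floor,orientation Passed to [quantify_traces()].
#' @return A list with `results` (a `significance_result`), `summary` (from
#'   [summarize_run()]), `sample_table` and `control_table`
#'   (`editing_table`s), and `thresholds` (every decision threshold used).
#' @export
call_editing <- function(sample_chroms, control_chroms, reference,
                         edit_mode = c("A_to_G", "C_to_T"),
                         min_replicates = 3, strict_criterion2 = FALSE,
                         min_total_area = 0, baseline = "window_min",
                         identity_floor = 0.7,
                         orientation = c("forward", "reverse")) {
  edit_mode <- match.arg(edit_mode)
  orientation <- match.arg(orientation)
  if (length(sample_chroms) < min_replicates)
    stop_sangeredit(sprintf("need at least %d sample replicates, got %d",
                            min_replicates, length(sample_chroms)),
                    "sangeredit_threshold_error")
  if (!length(control_chroms))
    stop_sangeredit("at least one control replicate is required",
                    "sangeredit_threshold_error")
  qs <- quantify_traces(sample_chroms, reference, baseline, identity_floor,
                        orientation)
  qc <- quantify_traces(control_chroms, reference, baseline, identity_floor,
                        orientation)
  candidates <- enumerate_candidates(reference, edit_mode)
  st <- build_editing_table(qs$peaks, qs$maps, candidates, "sample",
                            edit_mode, qs$ids, min_total_area)
  ct <- build_editing_table(qc$peaks, qc$maps, candidates, "control",
                            edit_mode, qc$ids, min_total_area)
  res <- call_significant_sites(st, ct, min_replicates, strict_criterion2)
  list(results = res, summary = summarize_run(res),
       sample_table = st, control_table = ct,
       thresholds = list(edit_mode = edit_mode,
                         min_replicates = min_replicates,
                         strict_criterion2 = strict_criterion2,
                         min_total_area = min_total_area,
                         baseline = baseline,
                         identity_floor = identity_floor,
                         orientation = orientation))
}

# Convenience for simulated experiments from simulate_experiment().
call_experiment <- function(experiment, ...) {
  call_editing(experiment$sample, experiment$control, experiment$reference,
               edit_mode = experiment$edit_mode, ...)
}

#' Write the JSON run summary
#'
#' @param run A list from [call_editing()] (or any list with `summary` and
#'   `thresholds`).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_summary <- function(run, path) {
  jsonlite::write_json(list(summary = run$summary,
                            thresholds = run$thresholds),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Plot an editing profile along the reference
#'
#' Percent editing for every candidate position along the amplicon, the
#' display used to present targeted-editing results: background (non
#' significant) sites in grey, significant sites highlighted in colour.
#'
#' @param results A `significance_result` data frame.
#' @param value Which per-site quantity to plot: `"corrected_mean"`
#'   (default) or `"raw_mean"`.
#' @param significant_color Colour for significant sites.
#' @return A `ggplot` object.
#' @export
plot_editing_profile <- function(results, value = c("corrected_mean", "raw_mean"),
                                 significant_color = "#c0392b") {
  value <- match.arg(value)
  df <- as.data.frame(results)
  if (!nrow(df))
    stop_sangeredit("no results to plot", "sangeredit_content_error")
  df <- df[!is.na(df$evaluable) & df$evaluable, , drop = FALSE]
  df$percent <- 100 * pmax(df[[value]], 0)
  df$status <- factor(ifelse(df$significant, "significant", "background"),
                      levels = c("background", "significant"))
  ggplot2::ggplot(df, ggplot2::aes(x = ref_position, y = percent,
                                   colour = status)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(
      values = c(background = "grey55", significant = significant_color),
      drop = FALSE) +
    ggplot2::labs(x = "Reference position (nt)",
                  y = "Editing (%)",
                  colour = NULL) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_classic()
}

#' Read a plain-text key=value run configuration
#'
#' Lines of the form `key = value`; `#` starts a comment. List-valued keys
#' (`sample`, `control`) take comma-separated paths.
#'
#' @param path Config file path.
#' @return A named list of character values (list keys split on commas).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop_sangeredit(paste0("config file not found: ", path),
                    "sangeredit_format_error")
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", lines))
  bad <- lines[vapply(kv, length, 0L) != 3L]
  if (length(bad))
    stop_sangeredit(paste0(path, ": malformed config line: ", bad[1]),
                    "sangeredit_schema_error")
  out <- stats::setNames(lapply(kv, function(m) trimws(m[3])),
                         vapply(kv, function(m) m[2], ""))
  for (key in intersect(c("sample", "control"), names(out)))
    out[[key]] <- trimws(strsplit(out[[key]], ",")[[1]])
  out
}
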