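# The core statistic: per-site relative editing from peak areas, background
# correction against control replicates, and the two significance criteria
# applied across biological replicates:
#   1) the corrected editing mean must lie more than three times its
#      replicate standard deviation above zero;
#   2) the uncorrected editing mean must be at least twice the control mean
#      at that position.

#' Relative editing ratio from per-channel peak areas
#'
#' For A-to-G editing the ratio is G/(A+G); for C-to-T it is T/(C+T).
#' When the substrate + product area sum falls below `min_total_area`
#' (default 0, i.e. only an exactly-zero sum) the value is missing rather
#' than an error: no signal is not evidence of no editing.
#'
#' @param areas Named numeric vector (or matrix with columns) `A`, `C`, `G`,
#'   `T` of non-negative peak areas.
#' @param edit_mode `"A_to_G"` or `"C_to_T"`.
#' @param min_total_area Minimum substrate+product area required to report a
#'   ratio.
#' @return Numeric in `[0, 1]`, or `NA` when below the signal floor. For a
#'   matrix input, one value per row.
#' @export
editing_ratio <- function(areas, edit_mode = c("A_to_G", "C_to_T"),
                          min_total_area = 0) {
  edit_mode <- match.arg(edit_mode)
  if (is.null(dim(areas))) areas <- matrix(areas, nrow = 1,
                                           dimnames = list(NULL, names(areas)))
  s <- areas[, edit_substrate(edit_mode)]
  p <- areas[, edit_product(edit_mode)]
  if (any(c(s, p) < 0, na.rm = TRUE))
    stop_sangeredit("peak areas must be non-negative", "sangeredit_value_error")
  total <- s + p
  out <- ifelse(is.na(total) | total <= 0 | total < min_total_area,
                NA_real_, p / total)
  unname(out)
}

peak_table_areas <- function(peaks) {
  m <- as.matrix(as.data.frame(peaks)[, paste0("area_", CHANNEL_BASES)])
  colnames(m) <- CHANNEL_BASES
  m
}

#' Assemble a sites-by-replicates editing table
#'
#' Looks up each candidate site's peak areas in every replicate (via that
#' replicate's call-to-reference site map) and computes the relative editing
#' ratio. Sites not covered by a replicate's aligned calls are missing for
#' that replicate.
#'
#' Replicates may instead be given as externally quantified tables indexed
#' directly by reference position (raw-area or precomputed-ratio layouts
#' from [read_peak_table()]); pass `site_maps = NULL` in that case.
#'
#' @param peak_tables List of per-replicate `peak_quant_table`s (or
#'   `editing_ratio_table`s).
#' @param site_maps List of per-replicate `site_map`s from
#'   [align_basecalls()], parallel to `peak_tables`, or `NULL` when the
#'   tables are already in reference coordinates.
#' @param candidates A `candidate_sites` data frame from
#'   [enumerate_candidates()].
#' @param group `"sample"` or `"control"`.
#' @param edit_mode `"A_to_G"` or `"C_to_T"`.
#' @param replicate_ids Optional character vector of replicate names.
#' @param min_total_area Passed to [editing_ratio()].
#' @return An `editing_table`: list with `edit_mode`, `group`, `sites`
#'   (data frame), `replicate_ids`, and `values` (sites x replicates matrix
#'   of ratios in `[0,1]` with `NA` for unevaluable cells).
#' @export
build_editing_table <- function(peak_tables, site_maps, candidates,
                                group = c("sample", "control"),
                                edit_mode = c("A_to_G", "C_to_T"),
                                replicate_ids = NULL,
                                min_total_area = 0) {
  group <- match.arg(group)
  edit_mode <- match.arg(edit_mode)
  if (!length(peak_tables))
    stop_sangeredit("at least one replicate is required",
                    "sangeredit_insufficient_data_error")
  if (!is.null(site_maps) && length(site_maps) != length(peak_tables))
    stop_sangeredit("peak_tables and site_maps lengths differ",
                    "sangeredit_content_error")
  if (is.null(replicate_ids))
    replicate_ids <- paste0("rep", seq_along(peak_tables))

  sites <- as.data.frame(candidates)[, c("ref_position", "ref_base")]
  sites <- sites[order(sites$ref_position), , drop = FALSE]
  if (anyDuplicated(sites$ref_position))
    stop_sangeredit("candidate sites must be unique", "sangeredit_content_error")
  values <- matrix(NA_real_, nrow = nrow(sites), ncol = length(peak_tables),
                   dimnames = list(sites$ref_position, replicate_ids))

  for (r in seq_along(peak_tables)) {
    tab <- peak_tables[[r]]
    if (inherits(tab, "editing_ratio_table")) {
      idx <- match(sites$ref_position, tab$position)
      values[, r] <- tab$editing[idx]
      next
    }
    if (is.null(site_maps)) {
      if (!"position" %in% names(tab))
        stop_sangeredit(
          "peak table lacks reference positions and no site map was given",
          "sangeredit_content_error")
      idx <- match(sites$ref_position, tab$position)
    } else {
      sm <- site_maps[[r]]
      call_at <- sm$call_index[match(sites$ref_position, sm$ref_position)]
      idx <- match(call_at, tab$call_index)
    }
    has <- !is.na(idx)
    if (any(has))
      values[has, r] <- editing_ratio(
        peak_table_areas(tab)[idx[has], , drop = FALSE],
        edit_mode, min_total_area)
  }

  structure(list(edit_mode = edit_mode, group = group, sites = sites,
                 replicate_ids = replicate_ids, values = values),
            class = "editing_table")
}

#' @export
print.editing_table <- function(x, ...) {
  cat(sprintf("<editing_table> %s, %s: %d sites x %d replicates (%d missing cells)\n",
              x$edit_mode, x$group, nrow(x$values), ncol(x$values),
              sum(is.na(x$values))))
  invisible(x)
}

#' Call significant editing sites against control replicates
#'
#' For each candidate site the control mean is subtracted from every sample
#' replicate's raw editing value; the corrected mean and its
#' across-replicate sample standard deviation (n-1 denominator) feed the two
#' significance criteria:
#'
#' * criterion 1: `corrected_mean - 3 * corrected_sd > 0` (strict);
#' * criterion 2: `raw_mean >= 2 * control_mean`; when the control mean is
#'   numerically zero (below `eps`) the criterion holds iff `raw_mean > 0`.
#'
#' A site is significant only when both hold. Sites with fewer than
#' `min_replicates` non-missing sample values or no non-missing control
#' value are reported as not evaluable.
#'
#' @param sample,control `editing_table`s sharing `edit_mode` and site list.
#' @param min_replicates Minimum non-missing sample replicates per site
#'   (default 3, the lower end of typical biological-replicate designs).
#' @param strict_criterion2 If `TRUE`, criterion 2 must hold for every
#'   sample replicate individually rather than for the mean.
#' @param eps Numerical zero for the control mean.
#' @return A `significance_result` data frame: one row per site with
#'   `ref_position`, `ref_base`, per-replicate `raw_rep_*` columns,
#'   `n_sample`, `n_control`, `evaluable`, `raw_mean`, `control_mean`,
#'   `corrected_mean`, `corrected_sd`, `criterion1`, `criterion2`,
#'   `significant`.
#' @export
call_significant_sites <- function(sample, control, min_replicates = 3,
                                   strict_criterion2 = FALSE, eps = 1e-9) {
  stopifnot(inherits(sample, "editing_table"), inherits(control, "editing_table"))
  if (sample$edit_mode != control$edit_mode)
    stop_sangeredit("sample and control edit_mode differ",
                    "sangeredit_content_error")
  if (!identical(sample$sites$ref_position, control$sites$ref_position))
    stop_sangeredit("sample and control site lists differ",
                    "sangeredit_content_error")

  ns <- ncol(sample$values)
  out <- data.frame(ref_position = sample$sites$ref_position,
                    ref_base = sample$sites$ref_base,
                    stringsAsFactors = FALSE)
  raw <- sample$values
  colnames(raw) <- paste0("raw_rep_", seq_len(ns))
  out <- cbind(out, as.data.frame(raw))

  stat_names <- c("n_sample", "n_control", "evaluable", "raw_mean",
                  "control_mean", "corrected_mean", "corrected_sd",
                  "criterion1", "criterion2", "significant")
  res <- t(vapply(seq_len(nrow(raw)), function(i) {
    xs <- sample$values[i, ]
    xc <- control$values[i, ]
    xs <- xs[!is.na(xs)]
    xc <- xc[!is.na(xc)]
    if (length(xs) < min_replicates || length(xc) < 1L)
      return(c(n_sample = length(xs), n_control = length(xc), evaluable = 0,
               raw_mean = NA_real_, control_mean = NA_real_,
               corrected_mean = NA_real_, corrected_sd = NA_real_,
               criterion1 = NA, criterion2 = NA, significant = NA))
    control_mean <- mean(xc)
    raw_mean <- mean(xs)
    corrected <- xs - control_mean
    corrected_mean <- mean(corrected)
    corrected_sd <- stats::sd(corrected)
    crit1 <- (corrected_mean - 3 * corrected_sd) > 0
    crit2 <- if (strict_criterion2) {
      if (control_mean < eps) all(xs > 0) else all(xs >= 2 * control_mean)
    } else {
      if (control_mean < eps) raw_mean > 0 else raw_mean >= 2 * control_mean
    }
    c(n_sample = length(xs), n_control = length(xc), evaluable = 1,
      raw_mean = raw_mean, control_mean = control_mean,
      corrected_mean = corrected_mean, corrected_sd = corrected_sd,
      criterion1 = crit1, criterion2 = crit2,
      significant = crit1 && crit2)
  }, stats::setNames(numeric(10), stat_names)))
  if (!nrow(raw))
    res <- matrix(numeric(), 0, 10, dimnames = list(NULL, stat_names))

  out$n_sample <- as.integer(res[, "n_sample"])
  out$n_control <- as.integer(res[, "n_control"])
  out$evaluable <- res[, "evaluable"] == 1
  out$raw_mean <- res[, "raw_mean"]
  out$control_mean <- res[, "control_mean"]
  out$corrected_mean <- res[, "corrected_mean"]
  out$corrected_sd <- res[, "corrected_sd"]
  out$criterion1 <- ifelse(out$evaluable, res[, "criterion1"] == 1, NA)
  out$criterion2 <- ifelse(out$evaluable, res[, "criterion2"] == 1, NA)
  out$significant <- ifelse(out$evaluable, res[, "significant"] == 1, NA)
  class(out) <- c("significance_result", "data.frame")
  out
}

#' Summarise a significance-result collection
#'
#' @param results A `significance_result` data frame.
#' @return A list with `n_sites`, `n_evaluable`, `n_significant`,
#'   `max_corrected_mean` and `max_position` (ties broken by the smaller
#'   position; `NA` when nothing is evaluable).
#' @export
summarize_run <- function(results) {
  df <- as.data.frame(results)
  ev <- which(!is.na(df$evaluable) & df$evaluable)
  out <- list(n_sites = nrow(df),
              n_evaluable = length(ev),
              n_significant = sum(df$significant[ev]),
              max_corrected_mean = NA_real_,
              max_position = NA_integer_)
  if (length(ev)) {
    cm <- df$corrected_mean[ev]
    best <- ev[which(cm == max(cm))]
    best <- best[which.min(df$ref_position[best])]
    out$max_corrected_mean <- df$corrected_mean[best]
    out$max_position <- df$ref_position[best]
  }
  out
}
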