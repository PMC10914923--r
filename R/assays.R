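# Companion quantifications: (i) plasmid-mix calibration of peak-ratio
# linearity — templates carrying the reference and the edited base are mixed
# at known ratios, sequenced, and the measured peak-area fraction is
# regressed on the known mixing fraction; (ii) the CAPS assay — an
# engineered restriction site reports editing at one position, and the
# cleaved fraction of the amplicon is computed from Bioanalyzer band
# quantities and compared between groups with an unpaired two-tailed t-test.

#' Fit the peak-ratio calibration line
#'
#' Ordinary least squares of the measured editing fraction on the expected
#' (mixing-ratio) fraction. A slope near 1 with intercept near 0 and high
#' r-squared demonstrates that peak-area ratios respond linearly to template
#' composition down to low editing levels.
#'
#' @param series A data frame with columns `expected_fraction` and
#'   `measured_fraction` (e.g. from [read_calibration_table()]), at least 3
#'   points spanning at least 2 distinct expected values.
#' @return A list with `slope`, `intercept`, `r_squared`, `n`, and the
#'   underlying `lm` fit.
#' @export
fit_calibration <- function(series) {
  df <- as.data.frame(series)
  stopifnot(all(c("expected_fraction", "measured_fraction") %in% names(df)))
  df <- df[stats::complete.cases(df[, c("expected_fraction", "measured_fraction")]), ]
  if (nrow(df) < 3L)
    stop_sangeredit("calibration needs at least 3 points",
                    "sangeredit_insufficient_data_error")
  if (length(unique(df$expected_fraction)) < 2L)
    stop_sangeredit("all expected fractions identical: slope is not estimable",
                    "sangeredit_degenerate_design_error")
  fit <- stats::lm(measured_fraction ~ expected_fraction, data = df)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((df$measured_fraction - mean(df$measured_fraction))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = max(0, min(1, r2)),
       n = nrow(df),
       fit = fit)
}

match_band <- function(bands, expected_length, tolerance) {
  tol_nt <- expected_length * tolerance
  hits <- which(abs(bands$length_nt - expected_length) <= tol_nt)
  if (!length(hits)) return(NULL)
  # closest in length wins; ties by larger quantity
  hits[order(abs(bands$length_nt[hits] - expected_length),
             -bands$quantity[hits])][1]
}

#' Cleaved fraction of a digested CAPS lane
#'
#' Matches the lane's bands to the expected uncleaved amplicon length and to
#' the expected cleavage-fragment lengths (within a relative length
#' tolerance), then computes
#' `cleaved / (cleaved + uncleaved)` on molar quantities. Only the larger
#' matched cleavage fragment is counted, since a single cut yields two
#' fragments from one molecule and summing both would double count.
#'
#' @param lane A `band_table` (one lane, `treatment == "digested"`).
#' @param uncleaved_length Expected full-length amplicon size (nt).
#' @param cleaved_lengths Expected cleavage-fragment sizes (nt).
#' @param tolerance Relative band-size matching tolerance (default 0.1,
#'   i.e. 10%).
#' @param undigested Optional `band_table` for the matching undigested
#'   control lane; if given, it must contain a band at the uncleaved length
#'   or the assay is considered failed.
#' @return Cleaved fraction in `[0, 1]`, or `NA` when no quantity matched.
#' @export
caps_cleaved_fraction <- function(lane, uncleaved_length, cleaved_lengths,
                                  tolerance = 0.1, undigested = NULL) {
  lane <- as.data.frame(lane)
  if ("treatment" %in% names(lane) && !all(lane$treatment == "digested"))
    stop_sangeredit("lane must contain only digested bands",
                    "sangeredit_content_error")
  if (!is.null(undigested)) {
    und <- as.data.frame(undigested)
    if (is.null(match_band(und, uncleaved_length, tolerance)))
      stop_sangeredit(
        "undigested control lane lacks a band at the uncleaved length: assay failure",
        "sangeredit_assay_error")
  }
  iu <- match_band(lane, uncleaved_length, tolerance)
  uncleaved <- if (is.null(iu)) 0 else lane$quantity[iu]
  cl_hits <- vapply(sort(cleaved_lengths, decreasing = TRUE), function(len) {
    i <- match_band(lane, len, tolerance)
    if (is.null(i)) NA_real_ else lane$quantity[i]
  }, 0)
  cleaved <- if (all(is.na(cl_hits))) 0 else cl_hits[which(!is.na(cl_hits))[1]]
  total <- cleaved + uncleaved
  if (total <= 0) return(NA_real_)
  cleaved / total
}

#' Compare cleaved fractions between two groups (unpaired t-test)
#'
#' Two-sample, two-tailed t-test of the per-lane cleaved fractions; Welch's
#' unequal-variance form by default, switchable to the pooled-variance form.
#' Degenerate inputs where both groups have zero variance are handled in
#' closed form (`t = 0, p = 1` for equal means; `|t| = Inf, p = 0`
#' otherwise) rather than erroring.
#'
#' @param group_a,group_b Numeric vectors of cleaved fractions, each of
#'   length >= 2.
#' @param var_equal Use the pooled-variance (Student) form instead of Welch.
#' @return A list with `t`, `df`, `p_value`, `mean_a`, `mean_b`, `sd_a`,
#'   `sd_b`, `n_a`, `n_b`, `method`.
#' @export
compare_caps_groups <- function(group_a, group_b, var_equal = FALSE) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop_sangeredit("each group needs at least 2 values",
                    "sangeredit_insufficient_data_error")
  base <- list(mean_a = mean(group_a), mean_b = mean(group_b),
               sd_a = stats::sd(group_a), sd_b = stats::sd(group_b),
               n_a = length(group_a), n_b = length(group_b),
               method = if (var_equal) "student" else "welch")
  if (base$sd_a == 0 && base$sd_b == 0) {
    if (base$mean_a == base$mean_b)
      return(c(list(t = 0, df = NA_real_, p_value = 1), base))
    return(c(list(t = sign(base$mean_a - base$mean_b) * Inf,
                  df = NA_real_, p_value = 0), base))
  }
  tt <- stats::t.test(group_a, group_b, var.equal = var_equal,
                      alternative = "two.sided")
  c(list(t = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value), base)
}
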