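# Synthetic four-channel electropherograms with known ground-truth editing.
# Each reference base contributes one Gaussian peak at uniform spacing; at an
# edited position with fraction f the substrate channel carries (1-f) of the
# peak and the product channel f, mimicking the mixed template population in
# an RT-PCR amplicon. Symmetric inter-channel crosstalk and additive Gaussian
# channel noise produce the nonzero background that control subtraction must
# remove. The generator models the trace, not the biochemistry: no PCR bias,
# no RT errors, no mobility wobble unless jitter is requested.

#' Trace-model parameters for the chromatogram simulator
#'
#' @param peak_spacing Samples between adjacent called peaks (default 12).
#' @param peak_sd Gaussian peak standard deviation in samples (default 3).
#' @param amplitude Mean peak amplitude in fluorescence units (default 1000).
#' @param amplitude_cv Relative peak-to-peak amplitude variation (default
#'   0.1); the factor is shared by the substrate and product channels at an
#'   edited position, as both derive from the same molecule population.
#' @param crosstalk Fraction of each peak leaking into each of the other
#'   three channels (default 0.01); the emitting channel retains
#'   `1 - 3 * crosstalk`.
#' @param noise_sd Additive Gaussian channel noise, fluorescence units
#'   (default 10).
#' @param jitter_sd Peak-centre jitter in samples (default 0: uniform
#'   spacing, keeping closed-form expectations exact).
#' @return A `trace_model` list.
#' @export
trace_model <- function(peak_spacing = 12, peak_sd = 3, amplitude = 1000,
                        amplitude_cv = 0.1, crosstalk = 0.01, noise_sd = 10,
                        jitter_sd = 0) {
  pars <- list(peak_spacing = peak_spacing, peak_sd = peak_sd,
               amplitude = amplitude, amplitude_cv = amplitude_cv,
               crosstalk = crosstalk, noise_sd = noise_sd,
               jitter_sd = jitter_sd)
  if (any(unlist(pars) < 0))
    stop_sangeredit("trace model parameters must be non-negative",
                    "sangeredit_value_error")
  if (crosstalk >= 1 / 3)
    stop_sangeredit("crosstalk must be below 1/3", "sangeredit_value_error")
  # FWHM overlap warning: adjacent peaks closer than one full width at half
  # maximum overlap heavily and windows no longer isolate single bases.
  if (peak_spacing < 2 * sqrt(2 * log(2)) * peak_sd)
    warning("peak spacing below the peak FWHM: adjacent peaks overlap >= 50%")
  structure(pars, class = "trace_model")
}

check_edits <- function(reference, edits, edit_mode) {
  if (is.null(edits) || !nrow(edits))
    return(data.frame(position = integer(), fraction = numeric()))
  stopifnot(all(c("position", "fraction") %in% names(edits)))
  refv <- strsplit(reference, "")[[1]]
  substrate <- edit_substrate(edit_mode)
  bad <- edits$position[refv[edits$position] != substrate]
  if (length(bad))
    stop_sangeredit(paste0("edit position(s) not at a ", substrate,
                           " in the reference: ", paste(bad, collapse = ",")),
                    "sangeredit_value_error")
  if (any(edits$fraction < 0 | edits$fraction > 1))
    stop_sangeredit("edit fractions must lie in [0,1]", "sangeredit_value_error")
  edits[, c("position", "fraction")]
}

#' Simulate a Sanger chromatogram with known editing
#'
#' @param reference Character scalar, the amplicon sequence (A/C/G/T only).
#' @param edits Data frame with columns `position` (1-based, must be
#'   substrate bases) and `fraction` (true editing level in `[0,1]`), or
#'   `NULL` for an unedited read.
#' @param edit_mode `"A_to_G"` or `"C_to_T"`.
#' @param model A [trace_model()].
#' @param seed Integer seed; identical inputs and seed give bit-identical
#'   traces.
#' @param sample_id Identifier stored in the chromatogram.
#' @return A [chromatogram()]. Basecalls take the maximum-area channel's
#'   base, or the two-base IUPAC code when the minor channel exceeds 25% of
#'   the major — the convention trace viewers use to flag secondary peaks.
#' @export
simulate_chromatogram <- function(reference, edits = NULL,
                                  edit_mode = c("A_to_G", "C_to_T"),
                                  model = trace_model(), seed = NULL,
                                  sample_id = "synthetic") {
  edit_mode <- match.arg(edit_mode)
  reference <- toupper(paste(reference, collapse = ""))
  refv <- strsplit(reference, "")[[1]]
  if (!length(refv))
    stop_sangeredit("reference must be non-empty", "sangeredit_content_error")
  if (!all(refv %in% CHANNEL_BASES))
    stop_sangeredit("reference must contain only A/C/G/T",
                    "sangeredit_content_error")
  edits <- check_edits(reference, edits, edit_mode)
  if (!is.null(seed)) set.seed(as.integer(seed))

  n <- length(refv)
  sp <- model$peak_spacing
  L <- as.integer(round(sp * (n + 1))) + 1L
  centers <- sp * seq_len(n)
  if (model$jitter_sd > 0)
    centers <- sort(centers + stats::rnorm(n, 0, model$jitter_sd))
  amp <- model$amplitude * pmax(stats::rnorm(n, 1, model$amplitude_cv), 0.05)

  frac <- rep(0, n)
  frac[edits$position] <- edits$fraction
  substrate <- edit_substrate(edit_mode)
  product <- edit_product(edit_mode)

  x <- seq_len(L) - 1
  S <- matrix(0, L, 4, dimnames = list(NULL, CHANNEL_BASES))
  half <- ceiling(6 * model$peak_sd)
  for (i in seq_len(n)) {
    c0 <- centers[i]
    lo <- max(1L, floor(c0) - half + 1L)
    hi <- min(L, ceiling(c0) + half + 1L)
    shape <- amp[i] * exp(-((x[lo:hi] - c0)^2) / (2 * model$peak_sd^2))
    b <- refv[i]
    if (b == substrate && frac[i] > 0) {
      S[lo:hi, substrate] <- S[lo:hi, substrate] + (1 - frac[i]) * shape
      S[lo:hi, product] <- S[lo:hi, product] + frac[i] * shape
    } else {
      S[lo:hi, b] <- S[lo:hi, b] + shape
    }
  }

  ct <- model$crosstalk
  mix <- matrix(ct, 4, 4); diag(mix) <- 1 - 3 * ct
  O <- S %*% mix
  if (model$noise_sd > 0)
    O <- O + matrix(stats::rnorm(length(O), 0, model$noise_sd), nrow = L)
  O[O < 0] <- 0
  colnames(O) <- CHANNEL_BASES

  ploc <- as.integer(round(centers))
  halfwin <- floor(sp / 2)
  calls <- vapply(seq_len(n), function(i) {
    lo <- max(1L, ploc[i] - halfwin + 1L)
    hi <- min(L, ploc[i] + halfwin + 1L)
    sums <- colSums(O[lo:hi, , drop = FALSE])
    major <- which.max(sums)
    minor <- order(sums, decreasing = TRUE)[2]
    if (sums[minor] > 0.25 * sums[major])
      iupac_for_bases(CHANNEL_BASES[c(major, minor)])
    else CHANNEL_BASES[major]
  }, "")

  chromatogram(O, paste(calls, collapse = ""), ploc, sample_id = sample_id)
}

derive_seeds <- function(seed, n) {
  set.seed(as.integer(seed))
  sample.int(2147483646L, n)
}

#' Simulate a sample-vs-control replicate experiment
#'
#' Generates `n_sample` chromatograms carrying the specified true editing
#' and `n_control` chromatograms with all true fractions zero — the layout
#' of an editing assay with e.g. Luciferase-infiltrated controls. Each
#' replicate gets its own seed derived deterministically from the master
#' seed, so replicates differ in noise and amplitudes but the whole
#' experiment is reproducible.
#'
#' @inheritParams simulate_chromatogram
#' @param n_sample,n_control Replicate counts (each >= 1).
#' @param seed Master seed.
#' @return A list with `sample` and `control` (lists of chromatograms),
#'   `truth` (the edits data frame), `reference` and `edit_mode`.
#' @export
simulate_experiment <- function(reference, edits, edit_mode = c("A_to_G", "C_to_T"),
                                model = trace_model(), n_sample = 4,
                                n_control = 4, seed = 1) {
  edit_mode <- match.arg(edit_mode)
  stopifnot(n_sample >= 1, n_control >= 1)
  seeds <- derive_seeds(seed, n_sample + n_control)
  samples <- lapply(seq_len(n_sample), function(i)
    simulate_chromatogram(reference, edits, edit_mode, model,
                          seed = seeds[i],
                          sample_id = paste0("sample_rep", i)))
  controls <- lapply(seq_len(n_control), function(i)
    simulate_chromatogram(reference, NULL, edit_mode, model,
                          seed = seeds[n_sample + i],
                          sample_id = paste0("control_rep", i)))
  list(sample = samples, control = controls,
       truth = check_edits(toupper(reference), edits, edit_mode),
       reference = toupper(paste(reference, collapse = "")),
       edit_mode = edit_mode)
}

#' Reference with isolated candidate sites for simulation studies
#'
#' Repeats a five-base motif with exactly one substrate base, flanked by
#' bases whose channels do not enter the editing ratio; adjacent-peak tails
#' then cannot contaminate the substrate/product areas, keeping per-site
#' expectations clean. One candidate in five bases also keeps the read
#' alignable even when every candidate is fully edited.
#'
#' @param n_sites Number of candidate sites.
#' @param edit_mode `"A_to_G"` or `"C_to_T"`.
#' @return A list with `reference` (character) and `positions` (1-based
#'   candidate positions).
#' @export
synthetic_reference <- function(n_sites, edit_mode = c("A_to_G", "C_to_T")) {
  edit_mode <- match.arg(edit_mode)
  motif <- if (edit_mode == "A_to_G") "CATCT" else "ACGGA"
  list(reference = strrep(motif, n_sites),
       positions = 5L * seq_len(n_sites) - 3L)
}

#' Monte-Carlo operating characteristics of the significance criteria
#'
#' For each true editing fraction on a grid, simulates complete
#' sample-vs-control experiments, runs the full quantification and calling
#' pipeline, and reports the per-site significant-call rate: the type-I
#' error rate at f = 0 and the power at f > 0. Binomial standard errors are
#' included.
#'
#' @param fractions Numeric grid of true editing fractions.
#' @param n_sites Candidate sites per simulated amplicon.
#' @param model A [trace_model()].
#' @param n_sample,n_control Replicates per group.
#' @param n_runs Independent experiments per fraction.
#' @param seed Master seed.
#' @param edit_mode `"A_to_G"` or `"C_to_T"`.
#' @param min_replicates Passed to [call_significant_sites()].
#' @return Data frame with one row per fraction: `fraction`, `n_evaluated`,
#'   `n_called`, `call_rate`, `se` (binomial), `mean_raw`,
#'   `mean_corrected`.
#' @export
estimate_operating_characteristics <- function(fractions = c(0, 0.05, 0.1, 0.25, 0.5, 0.75, 1),
                                               n_sites = 40,
                                               model = trace_model(),
                                               n_sample = 4, n_control = 4,
                                               n_runs = 2, seed = 1,
                                               edit_mode = c("A_to_G", "C_to_T"),
                                               min_replicates = 3) {
  edit_mode <- match.arg(edit_mode)
  stopifnot(n_runs >= 1)
  ref <- synthetic_reference(n_sites, edit_mode)
  run_seeds <- matrix(derive_seeds(seed, length(fractions) * n_runs),
                      nrow = length(fractions))

  rows <- lapply(seq_along(fractions), function(fi) {
    f <- fractions[fi]
    called <- 0L; evaluated <- 0L
    raw_sum <- 0; corr_sum <- 0; n_val <- 0L
    for (r in seq_len(n_runs)) {
      edits <- data.frame(position = ref$positions, fraction = f)
      exp_ <- simulate_experiment(ref$reference, edits, edit_mode, model,
                                  n_sample, n_control,
                                  seed = run_seeds[fi, r])
      res <- call_experiment(exp_, min_replicates = min_replicates)$results
      ev <- !is.na(res$evaluable) & res$evaluable
      evaluated <- evaluated + sum(ev)
      called <- called + sum(res$significant[ev])
      raw_sum <- raw_sum + sum(res$raw_mean[ev])
      corr_sum <- corr_sum + sum(res$corrected_mean[ev])
      n_val <- n_val + sum(ev)
    }
    rate <- if (evaluated) called / evaluated else NA_real_
    data.frame(fraction = f, n_evaluated = evaluated, n_called = called,
               call_rate = rate,
               se = if (evaluated) sqrt(rate * (1 - rate) / evaluated) else NA_real_,
               mean_raw = if (n_val) raw_sum / n_val else NA_real_,
               mean_corrected = if (n_val) corr_sum / n_val else NA_real_)
  })
  do.call(rbind, rows)
}

#' Write a ground-truth editing table
#'
#' @param edits Data frame with `position` and `fraction`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(edits, path) {
  utils::write.table(edits[, c("position", "fraction")], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
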