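# Per-base peak-area integration. Each called peak owns a window reaching
# from the midpoint to its left neighbour to the midpoint to its right
# neighbour (half-open; the first and last windows are extended symmetrically
# outwards). Window areas are trapezoidal integrals of the linearly
# interpolated trace, so with no baseline correction the windows tile the
# span exactly and per-channel areas are conservative by construction.

# Cumulative trapezoidal integral of y at a (possibly fractional) sample
# coordinate t, with x = 0, 1, ..., length(y)-1.
cum_trapz_at <- function(y, t) {
  n <- length(y)
  csum <- c(0, cumsum((y[-1] + y[-n]) / 2))
  t <- pmin(pmax(t, 0), n - 1)
  k <- pmin(floor(t), n - 2)
  frac <- t - k
  yk <- y[k + 1]
  yk1 <- y[k + 2]
  yt <- yk + frac * (yk1 - yk)
  csum[k + 1] + frac * (yk + yt) / 2
}

# Minimum of the linearly interpolated signal over [a, b].
window_min_value <- function(y, a, b) {
  n <- length(y)
  a <- min(max(a, 0), n - 1)
  b <- min(max(b, 0), n - 1)
  interp <- function(t) {
    k <- min(floor(t), n - 2)
    y[k + 1] + (t - k) * (y[k + 2] - y[k + 1])
  }
  lo <- ceiling(a); hi <- floor(b)
  inner <- if (hi >= lo) min(y[(lo:hi) + 1]) else Inf
  min(inner, interp(a), interp(b))
}

#' Integrate per-base four-channel peak areas from a chromatogram
#'
#' Turns a trace into the per-called-base A/C/G/T peak areas that the
#' relative-editing ratio is computed from. The window of call *i* spans the
#' midpoints between neighbouring called peaks (first and last windows
#' extended symmetrically); per channel, the area is the trapezoidal integral
#' of the trace over the window. With `baseline = "window_min"` (the
#' default) the window's per-channel minimum is subtracted before
#' integration, suppressing constant channel offsets; areas are clipped at
#' zero.
#'
#' @param chrom A [chromatogram()] with at least two basecalls.
#' @param baseline `"window_min"` (default) or `"none"`.
#' @return A `peak_quant_table` data frame with columns `call_index`
#'   (0-based), `called_base`, `window_start`, `window_end` (trace
#'   coordinates, half-open) and `area_A` .. `area_T`.
#' @export
integrate_called_peaks <- function(chrom, baseline = c("window_min", "none")) {
  stopifnot(inherits(chrom, "chromatogram"))
  baseline <- match.arg(baseline)
  p <- chrom$peak_locations
  n <- length(p)
  if (n < 2L)
    stop_sangeredit("need at least 2 basecalls to define integration windows",
                    "sangeredit_insufficient_data_error")
  L <- nrow(chrom$traces)
  bounds <- c(p[1] - (p[2] - p[1]) / 2,
              (p[-n] + p[-1]) / 2,
              p[n] + (p[n] - p[n - 1]) / 2)
  bounds <- pmin(pmax(bounds, 0), L - 1)

  areas <- matrix(0, nrow = n, ncol = 4, dimnames = list(NULL, CHANNEL_BASES))
  widths <- diff(bounds)
  for (ch in CHANNEL_BASES) {
    y <- chrom$traces[, ch]
    cums <- cum_trapz_at(y, bounds)
    a <- diff(cums)
    if (baseline == "window_min") {
      mins <- vapply(seq_len(n), function(i)
        window_min_value(y, bounds[i], bounds[i + 1]), 0)
      a <- a - mins * widths
    }
    areas[, ch] <- pmax(a, 0)
  }

  out <- data.frame(call_index = seq_len(n) - 1L,
                    called_base = strsplit(chrom$basecalls, "")[[1]],
                    window_start = bounds[-(n + 1)],
                    window_end = bounds[-1],
                    stringsAsFactors = FALSE)
  out[paste0("area_", CHANNEL_BASES)] <- as.data.frame(areas)
  names(out)[names(out) %in% paste0("area_", CHANNEL_BASES)] <-
    paste0("area_", CHANNEL_BASES)
  class(out) <- c("peak_quant_table", "data.frame")
  out
}
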