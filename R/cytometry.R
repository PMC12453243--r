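#' GFP-positive fraction of a flow-cytometry sample
#'
#' Gates the sample against a non-fluorescent control run alongside it: the
#' threshold is a high quantile of the control's green-channel distribution
#' (default the 99.9th percentile), and the result is the percentage of
#' sample events above it. Because the gate is set on quantiles it is
#' invariant under any strictly monotone transform applied to both sample and
#' control.
#'
#' @param sample,control numeric vectors of per-event green fluorescence.
#' @param gate_quantile control quantile defining the threshold.
#' @return percentage of GFP-positive events in `[0, 100]`.
#' @export
gfp_positive_fraction <- function(sample, control, gate_quantile = 0.999) {
  if (length(sample) < 1L || length(control) < 1L)
    stop("empty event table", call. = FALSE)
  threshold <- stats::quantile(control, gate_quantile, type = 7, names = FALSE)
  100 * mean(sample > threshold)
}

#' Mean fluorescence intensity (MFI)
#'
#' @param sample numeric vector of per-event fluorescence.
#' @return arithmetic mean of the channel.
#' @export
mfi <- function(sample) {
  if (length(sample) < 1L)
    stop("empty event table", call. = FALSE)
  mean(sample)
}

#' Locate the 1C and 2C peaks of a DNA-content histogram
#'
#' Smooths the per-event DNA-content values with a Gaussian kernel density
#' (Silverman's rule-of-thumb bandwidth by default), finds all local maxima,
#' and returns the positions of the two most prominent (highest-density)
#' ones; the smaller position is the 1C (unreplicated) peak and the larger
#' the 2C (replicated) peak.
#'
#' @param dna numeric vector of per-event DNA content (>= 1000 events).
#' @param bw kernel bandwidth, passed to [stats::density()].
#' @param n_grid density grid size.
#' @return named numeric vector `c(c1 = ..., c2 = ...)`.
#' @export
find_1c_2c_peaks <- function(dna, bw = "nrd0", n_grid = 512L) {
  if (length(dna) < 1000L)
    stop("need at least 1000 events for peak finding", call. = FALSE)
  d <- stats::density(dna, bw = bw, n = n_grid)
  y <- d$y
  is_max <- c(FALSE, y[2:(length(y) - 1L)] > y[1:(length(y) - 2L)] &
                     y[2:(length(y) - 1L)] >= y[3:length(y)], FALSE)
  peaks_x <- d$x[is_max]
  peaks_y <- y[is_max]
  if (length(peaks_x) < 2L)
    stop("fewer than two detectable peaks: degenerate histogram",
         call. = FALSE)
  top2 <- order(peaks_y, decreasing = TRUE)[1:2]
  pos <- sort(peaks_x[top2])
  c(c1 = pos[1L], c2 = pos[2L])
}

#' Percent cell-cycle progression
#'
#' `%progression = ((H - 1C) / (2C - 1C)) * 100`, where H is the sample's
#' mean DNA content and 1C/2C are the fitted peak positions. A sample of pure
#' G1 cells scores 0, pure G2/M scores 100; values outside `[0, 100]` are
#' possible for out-of-range H and are reported as-is.
#'
#' @param H mean DNA content of the sample (histogram MFI).
#' @param c1,c2 1C and 2C peak positions, `c1 < c2`.
#' @return percent progression.
#' @export
percent_progression <- function(H, c1, c2) {
  if (c1 >= c2)
    stop("1C peak must lie below 2C peak", call. = FALSE)
  (H - c1) / (c2 - c1) * 100
}

#' S-phase fraction from a DNA-content histogram
#'
#' Places symmetric windows of half-width `w * (c2 - c1) / 2` around the 1C
#' and 2C peaks and reports the percentage of events falling strictly between
#' the windows — cells with intermediate DNA content, i.e. replicating their
#' genome. `w` is a fraction of the inter-peak distance; widening it shrinks
#' the S-phase interval. The interval gate slightly undercounts a true
#' S-phase bridge because the peak windows truncate its ends, partially
#' offset by peak-tail spill-in; see the methods vignette.
#'
#' @param dna numeric vector of per-event DNA content.
#' @param c1,c2 1C and 2C peak positions.
#' @param w gate half-width as a fraction of `c2 - c1` (default 0.2).
#' @return percentage of events in the S-phase interval.
#' @export
s_phase_fraction <- function(dna, c1, c2, w = 0.2) {
  if (c1 >= c2) stop("1C peak must lie below 2C peak", call. = FALSE)
  if (w <= 0) stop("gate half-width must be positive", call. = FALSE)
  half <- w * (c2 - c1) / 2
  lo <- c1 + half
  hi <- c2 - half
  if (lo >= hi)
    stop("peak windows overlap: gate half-width too large", call. = FALSE)
  100 * mean(dna > lo & dna < hi)
}

#' Cumulative generations from serial-dilution growth records
#'
#' Each growth cycle between dilutions contributes
#' `log2(OD_end / OD_start)` doublings; cycles where the culture declined
#' contribute negatively. Additive over concatenated cycles.
#'
#' @param od_start,od_end positive optical densities at the start and end of
#'   each cycle (equal-length vectors).
#' @return total generations (doublings).
#' @export
cumulative_generations <- function(od_start, od_end) {
  if (length(od_start) != length(od_end))
    stop("od_start and od_end must have equal length", call. = FALSE)
  if (any(od_start <= 0) || any(od_end <= 0))
    stop("optical densities must be positive", call. = FALSE)
  sum(log2(od_end / od_start))
}

#' Per-sample cytometry summary
#'
#' Convenience wrapper computing the quantities reported per flow sample:
#' GFP-positive percentage (when a control is given), MFI, and — when a DNA
#' channel is present — the 1C/2C peaks, percent progression and S-phase
#' percentage.
#'
#' @param events data.frame with column `green` and optionally `dna`.
#' @param control optional data.frame with column `green` from the
#'   non-fluorescent control.
#' @param w S-phase gate half-width (see [s_phase_fraction()]).
#' @return one-row data.frame with columns `mfi`, `pct_gfp`, `c1`, `c2`,
#'   `pct_progression`, `pct_s` (NA where not computable).
#' @export
cytometry_summary <- function(events, control = NULL, w = 0.2) {
  stopifnot(is.data.frame(events), "green" %in% names(events))
  out <- data.frame(mfi = mfi(events$green), pct_gfp = NA_real_,
                    c1 = NA_real_, c2 = NA_real_,
                    pct_progression = NA_real_, pct_s = NA_real_)
  if (!is.null(control))
    out$pct_gfp <- gfp_positive_fraction(events$green, control$green)
  if ("dna" %in% names(events)) {
    pk <- find_1c_2c_peaks(events$dna)
    out$c1 <- pk[["c1"]]
    out$c2 <- pk[["c2"]]
    out$pct_progression <- percent_progression(mean(events$dna), pk[["c1"]],
                                               pk[["c2"]])
    out$pct_s <- s_phase_fraction(events$dna, pk[["c1"]], pk[["c2"]], w = w)
  }
  out
}
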