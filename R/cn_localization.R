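#' Quantile-skewness localization ratio of a cell's pixel intensities
#'
#' `ratio = ((q95 - median) - (median - q05)) / (q75 - q25)`, where q05, q25,
#' q75 and q95 are percentiles of the cell's GFP pixel intensities. The
#' statistic is a tail-asymmetry variant of Bowley's quantile skewness:
#' positive values indicate a long upper tail — a bright sub-population of
#' pixels, consistent with nuclear concentration of the reporter. Being built
#' from quantiles it is exactly invariant under positive affine transforms of
#' intensity and is zero for any symmetric pixel distribution. Quantiles use
#' linear interpolation between order statistics (type 7).
#'
#' @param pixels numeric vector of pixel intensities within one segmented
#'   cell.
#' @param min_pixels minimum pixel count (default 20; small cells give
#'   unstable extreme quantiles).
#' @return the localization ratio (dimensionless).
#' @export
localization_ratio <- function(pixels, min_pixels = 20L) {
  pixels <- pixels[is.finite(pixels)]
  if (length(pixels) < min_pixels)
    stop("too few pixels (", length(pixels), " < ", min_pixels, ")",
         call. = FALSE)
  q <- stats::quantile(pixels, c(0.05, 0.25, 0.5, 0.75, 0.95), type = 7,
                       names = FALSE)
  iqr <- q[4L] - q[2L]
  if (iqr == 0)
    stop("zero interquartile range: ratio undefined", call. = FALSE)
  ((q[5L] - q[3L]) - (q[3L] - q[1L])) / iqr
}

#' Per-cell localization ratios from a long-format pixel table
#'
#' @param pixel_table data.frame with columns `cell_id` and `pixel_value`
#'   (one row per pixel); an optional `frame_time_min` column is carried
#'   through (one ratio per cell per frame).
#' @param min_pixels forwarded to [localization_ratio()].
#' @return data.frame with columns `cell_id` (and `frame_time_min` if
#'   present) and `ratio`; cells failing the ratio preconditions are excluded
#'   with a warning.
#' @export
localization_ratios <- function(pixel_table, min_pixels = 20L) {
  stopifnot(is.data.frame(pixel_table),
            all(c("cell_id", "pixel_value") %in% names(pixel_table)))
  keys <- if ("frame_time_min" %in% names(pixel_table))
    interaction(pixel_table$cell_id, pixel_table$frame_time_min, drop = TRUE)
  else factor(pixel_table$cell_id)
  groups <- split(seq_len(nrow(pixel_table)), keys)
  rows <- lapply(groups, function(idx) {
    r <- tryCatch(localization_ratio(pixel_table$pixel_value[idx],
                                     min_pixels = min_pixels),
                  error = function(e) NA_real_)
    out <- data.frame(cell_id = pixel_table$cell_id[idx[1L]], ratio = r,
                      stringsAsFactors = FALSE)
    if ("frame_time_min" %in% names(pixel_table))
      out$frame_time_min <- pixel_table$frame_time_min[idx[1L]]
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  n_bad <- sum(is.na(res$ratio))
  if (n_bad > 0L)
    warning(n_bad, " cell(s) excluded (too few pixels or zero IQR)",
            call. = FALSE)
  res[!is.na(res$ratio), , drop = FALSE]
}

#' Percentage of cells with nuclear-localized reporter
#'
#' A cell is scored nuclear when its localization ratio exceeds the threshold
#' theta. The default theta = 0.5 is calibrated as roughly mean + 3 sd of the
#' ratio distribution from cells without a nuclear sub-population (it
#' replaces the manual visual scoring of nuclei with an explicit numeric
#' rule).
#'
#' @param ratios numeric vector of per-cell localization ratios.
#' @param theta nuclear-scoring threshold.
#' @return percentage of cells with `ratio > theta`.
#' @export
nuclear_fraction <- function(ratios, theta = 0.5) {
  ratios <- ratios[is.finite(ratios)]
  if (length(ratios) < 1L)
    stop("no scorable cells", call. = FALSE)
  100 * mean(ratios > theta)
}

#' Detect activity pulses in a single-cell localization trace
#'
#' A pulse is a maximal run of consecutive frames with ratio above theta.
#' Its duration is the run length times the frame interval (a one-frame
#' excursion lasts one interval), and it is classified brief when the
#' duration does not exceed `brief_max_minutes`. Sampling must be uniform;
#' cells are treated independently and a tracking gap would terminate any
#' open pulse upstream of this function.
#'
#' @param times frame times in minutes, strictly increasing, uniformly
#'   spaced (default spacing 0.5 min).
#' @param ratio localization ratio per frame.
#' @param theta pulse threshold.
#' @param brief_max_minutes maximal duration (min) classified as brief.
#' @param tol relative tolerance for spacing uniformity.
#' @return data.frame with columns `start`, `end`, `duration_min`,
#'   `peak_ratio`, `brief` (zero rows when no frame exceeds theta).
#' @export
detect_pulses <- function(times, ratio, theta = 0.5, brief_max_minutes = 5,
                          tol = 1e-6) {
  if (length(times) < 1L)
    stop("empty trace", call. = FALSE)
  if (length(times) != length(ratio))
    stop("times and ratio must have equal length", call. = FALSE)
  if (length(times) > 1L) {
    dt <- diff(times)
    if (any(dt <= 0) || any(abs(dt - dt[1L]) > tol * dt[1L]))
      stop("times must be strictly increasing and uniformly spaced",
           call. = FALSE)
    interval <- dt[1L]
  } else interval <- 0.5
  above <- ratio > theta
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  out <- data.frame(start = times[starts[keep]], end = times[ends[keep]],
                    duration_min = runs$lengths[keep] * interval,
                    peak_ratio = vapply(keep, function(i)
                      max(ratio[starts[i]:ends[i]]), numeric(1)))
  out$brief <- out$duration_min <= brief_max_minutes
  rownames(out) <- NULL
  out
}

#' Population summary of localization traces
#'
#' Per-frame mean localization ratio with a normal-approximation 95%
#' confidence interval (`mean +/- 1.96 sd / sqrt(n)`). Frames with fewer than
#' two cells are omitted with a warning.
#'
#' @param traces data.frame with columns `cell_id`, `time_min`, `ratio`.
#' @return data.frame with columns `time_min`, `n`, `mean`, `ci_lo`, `ci_hi`.
#' @export
population_summary <- function(traces) {
  stopifnot(is.data.frame(traces),
            all(c("cell_id", "time_min", "ratio") %in% names(traces)))
  by_frame <- split(traces$ratio, traces$time_min)
  n <- lengths(by_frame)
  if (any(n < 2L)) {
    warning(sum(n < 2L), " frame(s) with < 2 cells omitted", call. = FALSE)
    by_frame <- by_frame[n >= 2L]
  }
  if (length(by_frame) == 0L)
    stop("no frame has >= 2 cells", call. = FALSE)
  mu <- vapply(by_frame, mean, numeric(1))
  sdv <- vapply(by_frame, stats::sd, numeric(1))
  nn <- lengths(by_frame)
  half <- 1.96 * sdv / sqrt(nn)
  data.frame(time_min = as.numeric(names(by_frame)), n = nn, mean = mu,
             ci_lo = mu - half, ci_hi = mu + half, row.names = NULL)
}
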