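#' Convert a count matrix to frequencies
#'
#' Adds a pseudocount to every cell and normalizes each timepoint column to
#' sum to one. The pseudocount (default 0.5) keeps frequencies strictly
#' positive so log2 transforms are defined for variants that drop out of the
#' sequencing sample.
#'
#' @param counts nonnegative integer matrix, variants x timepoints, with
#'   rownames = genotypes and one row for the WT reference.
#' @param pseudocount nonnegative value added to every cell before
#'   normalization.
#' @return frequency matrix of the same shape; columns sum to 1.
#' @export
to_frequencies <- function(counts, pseudocount = 0.5) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers", call. = FALSE)
  if (ncol(counts) < 2L)
    stop("need at least 2 timepoints", call. = FALSE)
  adj <- counts + pseudocount
  colsum <- colSums(adj)
  if (any(colsum <= 0))
    stop("all-zero timepoint column with zero pseudocount: degenerate input",
         call. = FALSE)
  sweep(adj, 2L, colsum, "/")
}

# OLS slope/intercept/r2 of y against x, closed form
.ols <- function(x, y) {
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  c(slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]), r2 = r2)
}

#' Selection coefficient of one variant against the WT reference
#'
#' The selection coefficient is the ordinary-least-squares slope of
#' `log2 f_v(t) - log2 f_wt(t)` against time in hours: the rate at which the
#' variant's read fraction changes relative to wild type, in log2 units per
#' hour. On a common time grid this equals
#' `slope(log2 f_v) - slope(log2 f_wt)`. Positive values indicate a fitness
#' advantage over WT.
#'
#' @param f_v,f_wt strictly positive frequency vectors of equal length.
#' @param times timepoints in hours, strictly increasing, same length.
#' @return list with `s` (slope, /h), `intercept`, `r2`.
#' @export
selection_coefficient <- function(f_v, f_wt, times) {
  if (length(times) < 2L)
    stop("need at least 2 timepoints", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(f_v <= 0) || any(f_wt <= 0))
    stop("frequencies must be strictly positive", call. = FALSE)
  if (length(f_v) != length(times) || length(f_wt) != length(times))
    stop("frequency and time vectors must have equal length", call. = FALSE)
  y <- log2(f_v) - log2(f_wt)
  fit <- .ols(times, y)
  list(s = fit[["slope"]], intercept = fit[["intercept"]], r2 = fit[["r2"]])
}

#' Selection coefficients for every variant of one replicate
#'
#' Applies [selection_coefficient()] to each row of a frequency matrix
#' against the WT reference row.
#'
#' @param freqs frequency matrix (see [to_frequencies()]) with genotype
#'   rownames.
#' @param times timepoints in hours.
#' @param wt rowname of the WT reference (default `"WT"`).
#' @return data.frame with columns `genotype`, `s`, `intercept`, `r2`. The WT
#'   row has `s == 0` exactly.
#' @export
fit_selection <- function(freqs, times, wt = "WT") {
  if (!wt %in% rownames(freqs))
    stop("WT reference row '", wt, "' missing from frequency matrix",
         call. = FALSE)
  f_wt <- freqs[wt, ]
  res <- lapply(rownames(freqs), function(g)
    selection_coefficient(freqs[g, ], f_wt, times))
  data.frame(genotype = rownames(freqs),
             s = vapply(res, `[[`, numeric(1), "s"),
             intercept = vapply(res, `[[`, numeric(1), "intercept"),
             r2 = vapply(res, `[[`, numeric(1), "r2"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Log2 fold change relative to time zero, WT-normalized
#'
#' `L[v, t] = [log2 f_v(t) - log2 f_v(0)] - [log2 f_wt(t) - log2 f_wt(0)]`.
#' The first column is identically zero, and the OLS slope of each row
#' against time equals that variant's selection coefficient.
#'
#' @inheritParams fit_selection
#' @return matrix of the same shape as `freqs`.
#' @export
log2fc_vs_t0 <- function(freqs, wt = "WT") {
  if (!wt %in% rownames(freqs))
    stop("WT reference row '", wt, "' missing", call. = FALSE)
  if (any(freqs <= 0))
    stop("frequencies must be strictly positive", call. = FALSE)
  lf <- log2(freqs)
  lf <- lf - lf[, 1L]                        # per-variant change from t0
  sweep(lf, 2L, lf[wt, ], "-")               # normalize to WT
}

#' Selection coefficient from a pairwise co-culture trajectory
#'
#' In a two-strain co-culture the mutant fraction `p(t)` and the WT fraction
#' `1 - p(t)` share one denominator, so the log2 fold change of the mutant
#' relative to WT is the log2 odds `log2(p / (1 - p))`. The selection
#' coefficient is its OLS slope against time in hours. Fractions measured by
#' flow cytometry are clamped to `[1/(events + 1), 1 - 1/(events + 1)]`
#' before the logit — a Laplace-style bound, usable down to a single event —
#' so that a timepoint where one strain fell below detection does not produce
#' an infinite value.
#'
#' @param times timepoints in hours, strictly increasing.
#' @param fraction mutant fraction in `[0, 1]` per timepoint.
#' @param events number of cytometry events behind each fraction (clamp
#'   bound; default 5000).
#' @return list with `s` (/h), `intercept`, `r2`.
#' @export
pairwise_selection <- function(times, fraction, events = 5000L) {
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(fraction < 0 | fraction > 1))
    stop("fractions must lie in [0, 1]", call. = FALSE)
  p <- pmin(pmax(fraction, 1 / (events + 1)), 1 - 1 / (events + 1))
  if (any(p <= 0 | p >= 1))
    stop("fraction degenerate after clamping", call. = FALSE)
  y <- log2(p / (1 - p))
  fit <- .ols(times, y)
  list(s = fit[["slope"]], intercept = fit[["intercept"]], r2 = fit[["r2"]])
}

#' Average selection coefficients over biological replicates
#'
#' @param s_values numeric vector of per-replicate selection coefficients.
#' @return list with `mean`, `sd` (0 for a single replicate), `n`, and the
#'   input `replicates`. Input order is irrelevant.
#' @export
aggregate_replicates <- function(s_values) {
  s_values <- unlist(s_values, use.names = FALSE)
  if (length(s_values) < 1L)
    stop("need at least one replicate", call. = FALSE)
  list(mean = mean(s_values),
       sd = if (length(s_values) > 1L) stats::sd(s_values) else 0,
       n = length(s_values),
       replicates = s_values)
}

#' Pearson correlation of selection coefficients between two conditions
#'
#' @param s_A,s_B numeric vectors of equal length >= 3, e.g. per-genotype
#'   mean selection coefficients in two conditions.
#' @return Pearson product-moment correlation in `[-1, 1]`.
#' @export
condition_correlation <- function(s_A, s_B) {
  if (length(s_A) != length(s_B) || length(s_A) < 3L)
    stop("vectors must have equal length >= 3", call. = FALSE)
  if (!all(is.finite(s_A)) || !all(is.finite(s_B)))
    stop("inputs must be finite", call. = FALSE)
  if (stats::sd(s_A) == 0 || stats::sd(s_B) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  stats::cor(s_A, s_B, method = "pearson")
}
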