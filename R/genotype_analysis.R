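#' Box-plot style summary of a group of selection coefficients
#'
#' Quantiles use linear interpolation between order statistics
#' (`stats::quantile` type 7); this one convention is used throughout the
#' package. Whiskers follow the 1.5 IQR rule: they extend to the most extreme
#' data points within `q25 - 1.5 IQR` and `q75 + 1.5 IQR`, and points beyond
#' them are listed as outliers.
#'
#' @param values numeric vector.
#' @param key optional group label.
#' @return list with `key`, `n`, `median`, `q25`, `q75`, `whisker_lo`,
#'   `whisker_hi`, `outliers`.
#' @export
group_summary <- function(values, key = NA_character_) {
  values <- values[is.finite(values)]
  if (length(values) < 1L)
    stop("empty group", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3L] - q[1L]
  lo_fence <- q[1L] - 1.5 * iqr
  hi_fence <- q[3L] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  list(key = key, n = length(values),
       median = q[2L], q25 = q[1L], q75 = q[3L],
       whisker_lo = min(values[inside]), whisker_hi = max(values[inside]),
       outliers = sort(values[!inside]))
}

.summary_df <- function(summaries) {
  do.call(rbind, lapply(summaries, function(s)
    data.frame(key = s$key, n = s$n, median = s$median, q25 = s$q25,
               q75 = s$q75, whisker_lo = s$whisker_lo,
               whisker_hi = s$whisker_hi, n_outliers = length(s$outliers),
               stringsAsFactors = FALSE)))
}

.check_scheme_genotypes <- function(genotypes, scheme) {
  states <- c(scheme$low_state, scheme$high_state)
  chars <- strsplit(genotypes, "", fixed = TRUE)
  bad <- vapply(chars, function(x) any(!x %in% states), logical(1))
  if (any(bad))
    stop("genotype(s) outside scheme ", scheme$name, ": ",
         paste(utils::head(genotypes[bad], 5L), collapse = ", "),
         call. = FALSE)
  invisible(chars)
}

#' Group selection coefficients by mutation count
#'
#' Stratifies a full scheme library by the number of sites carrying a given
#' state (e.g. the number of phosphomimetic mutations), yielding one
#' [group_summary()] per count k = 0..n. Stratum sizes are the binomial
#' coefficients C(n, k).
#'
#' @param estimates data.frame with columns `genotype` and `s`, covering a
#'   full scheme library.
#' @param scheme a [library_scheme()].
#' @param state the state being counted (default the scheme's high state).
#' @return named list of group summaries, keys `"0"`..`"n"`.
#' @export
group_by_count <- function(estimates, scheme, state = scheme$high_state) {
  chars <- .check_scheme_genotypes(estimates$genotype, scheme)
  n <- nchar(estimates$genotype[1L])
  k <- vapply(chars, function(x) sum(x == state), integer(1))
  stats::setNames(
    lapply(0:n, function(kk)
      group_summary(estimates$s[k == kk], key = as.character(kk))),
    as.character(0:n))
}

#' Contrast selection coefficients by the state at one site
#'
#' Splits a full scheme library into the 2^(n-1) genotypes carrying the low
#' state at the given site versus the 2^(n-1) carrying the high state.
#'
#' @inheritParams group_by_count
#' @param site site label (must appear in `sites$label`).
#' @param sites site table defining ordinal positions.
#' @return list with elements `low` and `high`, each a [group_summary()].
#' @export
site_contrast <- function(estimates, site, sites, scheme) {
  idx <- match(site, sites$label)
  if (is.na(idx))
    stop("unknown site label: ", site, call. = FALSE)
  .check_scheme_genotypes(estimates$genotype, scheme)
  st <- substr(estimates$genotype, idx, idx)
  list(low = group_summary(estimates$s[st == scheme$low_state],
                           key = paste0(site, "=", scheme$low_state)),
       high = group_summary(estimates$s[st == scheme$high_state],
                            key = paste0(site, "=", scheme$high_state)))
}

# genotypes satisfying a site-label -> state constraint map
.match_constraints <- function(genotypes, constraints, sites) {
  idx <- match(names(constraints), sites$label)
  if (anyNA(idx))
    stop("unknown site label(s): ",
         paste(names(constraints)[is.na(idx)], collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(names(constraints)))
    stop("contradictory constraints: duplicated site labels", call. = FALSE)
  keep <- rep(TRUE, length(genotypes))
  for (j in seq_along(idx))
    keep <- keep & substr(genotypes, idx[j], idx[j]) == constraints[[j]]
  keep
}

#' Contrast two constrained genotype subsets
#'
#' Selects the genotypes satisfying each site-to-state constraint map (e.g.
#' all mutants phosphomimetic at both T428 and T440 versus all mutants wild
#' type at those positions) and summarizes each subset.
#'
#' @inheritParams site_contrast
#' @param constraints_A,constraints_B named character vectors mapping site
#'   labels to required states.
#' @return list with elements `A` and `B` ([group_summary()]s) and
#'   `values_A`, `values_B` (the underlying selection coefficients).
#' @export
subset_contrast <- function(estimates, constraints_A, constraints_B, sites) {
  in_A <- .match_constraints(estimates$genotype, constraints_A, sites)
  in_B <- .match_constraints(estimates$genotype, constraints_B, sites)
  if (!any(in_A) || !any(in_B))
    stop("a constraint set selects no genotypes", call. = FALSE)
  list(A = group_summary(estimates$s[in_A],
                         key = paste(names(constraints_A), constraints_A,
                                     sep = "=", collapse = ",")),
       B = group_summary(estimates$s[in_B],
                         key = paste(names(constraints_B), constraints_B,
                                     sep = "=", collapse = ",")),
       values_A = estimates$s[in_A], values_B = estimates$s[in_B])
}

#' Deterministic genotype ordering for fold-change heatmaps
#'
#' Orders genotypes first by the number of phosphomimetic (`E`) sites
#' ascending, then within each cluster by the control-condition log2 fold
#' change at the final timepoint ascending, with residual ties broken by
#' genotype string (lexicographic) so the order is a deterministic function
#' of the data.
#'
#' @param log2fc matrix from [log2fc_vs_t0()] under control conditions, rows
#'   keyed by genotype; if several replicate matrices are supplied in a list
#'   their mean is used.
#' @param genotypes genotypes to order (must all have rows in `log2fc`).
#' @return character vector: `genotypes` in heatmap order.
#' @export
heatmap_order <- function(log2fc, genotypes) {
  if (is.list(log2fc) && !is.matrix(log2fc))
    log2fc <- Reduce(`+`, log2fc) / length(log2fc)
  if (!all(genotypes %in% rownames(log2fc)))
    stop("missing genotype row(s) in log2fc matrix: ",
         paste(utils::head(setdiff(genotypes, rownames(log2fc)), 5L),
               collapse = ", "), call. = FALSE)
  n_E <- genotype_metrics(genotypes)$n_E
  final <- log2fc[genotypes, ncol(log2fc)]
  genotypes[order(n_E, final, genotypes)]
}

#' Two-group statistical contrast
#'
#' Conventional tests for comparing two groups of selection coefficients (or
#' any paired/unpaired measurements): two-sided Mann-Whitney (default,
#' `stats::wilcox.test`), Welch t, or paired t. `"anova-sidak"` delegates to
#' [anova_sidak()] with two groups. For the degenerate paired case where all
#' differences are zero the statistic is 0 and p = 1.
#'
#' @param a,b numeric vectors (equal length required when paired).
#' @param method one of `"mann-whitney"`, `"t"`, `"paired-t"`,
#'   `"anova-sidak"`.
#' @return list with `method`, `statistic`, `p_value`.
#' @export
contrast_test <- function(a, b,
                          method = c("mann-whitney", "t", "paired-t",
                                     "anova-sidak")) {
  method <- match.arg(method)
  if (length(a) < 2L || length(b) < 2L)
    stop("need at least 2 values per group", call. = FALSE)
  if (method == "paired-t" && length(a) != length(b))
    stop("paired test requires equal group sizes", call. = FALSE)
  res <- switch(method,
    "mann-whitney" = {
      w <- suppressWarnings(stats::wilcox.test(a, b))
      list(statistic = unname(w$statistic), p_value = w$p.value)
    },
    "t" = {
      tt <- stats::t.test(a, b)
      list(statistic = unname(tt$statistic), p_value = tt$p.value)
    },
    "paired-t" = {
      d <- a - b
      if (all(d == 0))
        list(statistic = 0, p_value = 1)
      else if (stats::sd(d) <= 1e-10 * max(abs(d)))
        # constant nonzero shift: the statistic diverges
        list(statistic = sign(mean(d)) * Inf, p_value = 0)
      else {
        tt <- stats::t.test(a, b, paired = TRUE)
        list(statistic = unname(tt$statistic), p_value = tt$p.value)
      }
    },
    "anova-sidak" = {
      fit <- anova_sidak(list(A = a, B = b))
      list(statistic = fit$F, p_value = fit$pairwise$p_sidak[1L])
    })
  c(list(method = method), res)
}

#' One-way ANOVA with Sidak-corrected pairwise comparisons
#'
#' Fits an ordinary one-way ANOVA across the groups, then performs all
#' pairwise Welch t tests with the Sidak multiplicity correction
#' `p_adj = 1 - (1 - p)^m` over the m comparisons.
#'
#' @param groups named list of numeric vectors.
#' @return list with `F`, `p_overall`, and `pairwise` (data.frame `group1`,
#'   `group2`, `p_raw`, `p_sidak`).
#' @export
anova_sidak <- function(groups) {
  if (length(groups) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  fit <- stats::aov(values ~ fac)
  tab <- summary(fit)[[1L]]
  pairs <- utils::combn(names(groups), 2L)
  m <- ncol(pairs)
  p_raw <- apply(pairs, 2L, function(pr)
    stats::t.test(groups[[pr[1L]]], groups[[pr[2L]]])$p.value)
  data <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                     p_raw = p_raw, p_sidak = pmin(1, 1 - (1 - p_raw)^m),
                     stringsAsFactors = FALSE)
  list(F = tab[["F value"]][1L], p_overall = tab[["Pr(>F)"]][1L],
       pairwise = data)
}
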