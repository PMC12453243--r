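test_that("group summaries agree with a sort-based quantile oracle", {
  set.seed(21)
  for (i in 1:5) {
    x <- rnorm(50)
    g <- group_summary(x)
    # brute-force type-7 quantile: linear interpolation on sorted values
    q7 <- function(p) {
      xs <- sort(x); h <- (length(xs) - 1) * p
      lo <- floor(h) + 1
      xs[lo] + (h - floor(h)) * (xs[min(lo + 1, length(xs))] - xs[lo])
    }
    expect_equal(g$median, q7(0.5), tolerance = 1e-12)
    expect_equal(g$q25, q7(0.25), tolerance = 1e-12)
    expect_equal(g$q75, q7(0.75), tolerance = 1e-12)
    expect_lte(g$q25, g$median); expect_lte(g$median, g$q75)
    expect_gte(g$whisker_lo, min(x)); expect_lte(g$whisker_hi, max(x))
    expect_true(all(g$outliers < g$whisker_lo | g$outliers > g$whisker_hi))
  }
  # constant data: median = constant, no outliers
  gc <- group_summary(rep(0.2, 10))
  expect_equal(gc$median, 0.2)
  expect_length(gc$outliers, 0)
})

test_that("mutation-count groups have binomial sizes and detect planted monotone fitness", {
  n_E <- genotype_metrics(fx8$genotypes)$n_E
  est <- data.frame(genotype = fx8$genotypes,
                    s = 0.01 * n_E + rnorm(256, sd = 1e-4))
  grp <- group_by_count(est, fx8$scheme, state = "E")
  expect_equal(vapply(grp, `[[`, numeric(1), "n"),
               setNames(choose(8, 0:8), as.character(0:8)))
  expect_equal(sum(vapply(grp, `[[`, numeric(1), "n")), 256)
  meds <- vapply(grp, `[[`, numeric(1), "median")
  expect_true(all(diff(meds) > 0))  # planted s proportional to n_E
  expect_error(group_by_count(data.frame(genotype = "WWWWWWWW", s = 0),
                              fx8$scheme), "outside scheme")
})

test_that("site contrasts halve the library and recover planted additive effects", {
  set.seed(33)
  n_site <- nchar(fx8$genotypes[1])
  states <- do.call(rbind, strsplit(fx8$genotypes, ""))
  delta <- 0.02
  # additive model: E at T440 (ordinal 2) adds delta; other sites are null
  s <- delta * (states[, 2] == "E") + rnorm(256, sd = 1e-3)
  est <- data.frame(genotype = fx8$genotypes, s = s)
  ct <- site_contrast(est, "T440", fx8$sites, fx8$scheme)
  expect_equal(ct$low$n, 128)
  expect_equal(ct$high$n, 128)
  expect_lt(abs((ct$high$median - ct$low$median) - delta), 2e-3)
  # a null site shows no median shift beyond noise
  ct0 <- site_contrast(est, "T479", fx8$sites, fx8$scheme)
  expect_lt(abs(ct0$high$median - ct0$low$median), 5e-4)
  expect_error(site_contrast(est, "T999", fx8$sites, fx8$scheme), "unknown")
})

test_that("subset contrasts select exactly the constrained genotypes", {
  sites <- hcm1_tad_sites()
  scheme <- library_scheme("WT/E")
  genos <- enumerate_library(sites, scheme)
  set.seed(44)
  states <- do.call(rbind, strsplit(genos, ""))
  both_E <- states[, 1] == "E" & states[, 2] == "E"
  est <- data.frame(genotype = genos, s = -0.03 * both_E + rnorm(256, sd = 1e-3))
  ct <- subset_contrast(est,
                        constraints_A = c(T428 = "E", T440 = "E"),
                        constraints_B = c(T428 = "W", T440 = "W"),
                        sites)
  expect_equal(ct$A$n, 64)  # 2^6 free sites
  expect_equal(ct$B$n, 64)
  expect_lt(ct$A$median, ct$B$median)  # planted penalty on the EE subset
  # constraints pinning every site select a single genotype
  full <- setNames(strsplit(genos[7], "")[[1]], sites$label)
  one <- subset_contrast(est, full, c(T428 = "W"), sites)
  expect_equal(one$A$n, 1)
  expect_error(subset_contrast(est, c(T428 = "E", T428 = "W"),
                               c(T440 = "W"), sites), "contradictory")
})

test_that("heatmap ordering clusters by n_E, ranks by final log2FC, and is sort-invariant", {
  set.seed(55)
  genos <- enumerate_library(make_sites(4), library_scheme("A/E"))
  L <- matrix(rnorm(length(genos) * 4), ncol = 4,
              dimnames = list(genos, NULL))
  ord <- heatmap_order(L, genos)
  n_E <- genotype_metrics(ord)$n_E
  expect_true(all(diff(n_E) >= 0))                    # clusters ascending
  expect_equal(ord[1], "AAAA")
  expect_equal(ord[length(ord)], "EEEE")
  within <- split(ord, n_E)
  for (blk in within)
    expect_true(all(diff(L[blk, 4]) >= 0))            # ranked within cluster
  # permutation of input rows leaves the ordering unchanged
  perm <- sample(nrow(L))
  expect_identical(heatmap_order(L[perm, ], genos), ord)
  expect_identical(heatmap_order(L[perm, ], sample(genos)), ord)
  # ties broken lexicographically
  Lt <- matrix(0, nrow = length(genos), ncol = 2,
               dimnames = list(genos, NULL))
  ord_t <- heatmap_order(Lt, genos)
  for (blk in split(ord_t, genotype_metrics(ord_t)$n_E))
    expect_identical(blk, sort(blk))
  expect_error(heatmap_order(L[-1, ], genos), "missing genotype")
})

test_that("two-group contrasts behave at the degenerate and shifted cases", {
  a <- c(0.01, 0.02, 0.03, 0.04)
  ident <- contrast_test(a, a, method = "paired-t")
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)
  up <- contrast_test(a + 0.05, a, method = "paired-t")
  expect_gt(up$statistic, 0)
  dn <- contrast_test(a - 0.05, a, method = "paired-t")
  expect_lt(dn$statistic, 0)
  expect_error(contrast_test(1, a), "at least 2")
  expect_error(contrast_test(a, a[1:3], method = "paired-t"), "equal")
})

test_that("Mann-Whitney p agrees with an exhaustive permutation oracle", {
  a <- c(0.8, 1.4, 2.1, 3.3)
  b <- c(2.9, 3.8, 4.4, 5.1)
  res <- contrast_test(a, b, method = "mann-whitney")
  # oracle: enumerate all C(8,4) group assignments of the pooled values and
  # count rank-sum statistics at least as extreme (two-sided)
  pool <- c(a, b)
  combos <- combn(8, 4)
  obs <- sum(rank(pool)[1:4])
  perm_stats <- apply(combos, 2, function(idx) sum(rank(pool)[idx]))
  center <- 4 * (8 + 1) / 2
  p_perm <- mean(abs(perm_stats - center) >= abs(obs - center))
  expect_equal(res$p_value, p_perm, tolerance = 1e-12)
})

test_that("one-way ANOVA with Sidak correction matches manual formulas", {
  set.seed(66)
  g <- list(A = rnorm(6, 0), B = rnorm(6, 2), C = rnorm(6, 0.2))
  fit <- anova_sidak(g)
  # oracle: aov on the stacked data
  df <- data.frame(y = unlist(g), f = rep(names(g), each = 6))
  ref <- summary(aov(y ~ f, df))[[1]]
  expect_equal(fit$F, ref[["F value"]][1], tolerance = 1e-10)
  expect_equal(fit$p_overall, ref[["Pr(>F)"]][1], tolerance = 1e-10)
  m <- nrow(fit$pairwise)
  expect_equal(fit$pairwise$p_sidak,
               pmin(1, 1 - (1 - fit$pairwise$p_raw)^m))
  # two-group delegation via contrast_test
  ct <- contrast_test(g$A, g$B, method = "anova-sidak")
  expect_lt(ct$p_value, 0.05)
})
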