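test_that("frequency normalization matches forced arithmetic", {
  m <- matrix(c(1, 1, 1, 1), 2, dimnames = list(c("a", "WT"), NULL))
  expect_equal(unname(to_frequencies(m, pseudocount = 0)),
               matrix(0.5, 2, 2))
  m2 <- matrix(c(0, 10, 0, 10), 2, dimnames = list(c("a", "WT"), NULL))
  f2 <- to_frequencies(m2, pseudocount = 0.5)
  expect_equal(unname(f2[, 1]), c(0.5 / 11, 10.5 / 11))
  # column sums are 1 for any valid input
  set.seed(1)
  m3 <- matrix(rpois(40, 30), 10, 4)
  expect_equal(colSums(to_frequencies(m3)), rep(1, 4), tolerance = 1e-9)
  expect_true(all(to_frequencies(m3) > 0))
  expect_error(to_frequencies(matrix(-1, 2, 2)), "nonnegative")
  expect_error(to_frequencies(matrix(0, 2, 2), pseudocount = 0), "degenerate")
})

test_that("selection coefficient is zero against self and forced for known slopes", {
  times <- c(0, 24, 48, 72)
  f <- c(0.2, 0.25, 0.3, 0.25)
  expect_equal(selection_coefficient(f, f, times)$s, 0)
  # relative fraction doubling every 24 h: s = 1/24 per hour
  f_wt <- rep(0.1, 4)
  f_v <- f_wt * 2^(times / 24)
  est <- selection_coefficient(f_v, f_wt, times)
  expect_equal(est$s, 1 / 24, tolerance = 1e-12)
  expect_equal(est$r2, 1, tolerance = 1e-12)
  expect_error(selection_coefficient(c(1), c(1), c(0)), "2 timepoints")
  expect_error(selection_coefficient(c(0.1, 0), c(0.1, 0.1), c(0, 24)),
               "positive")
})

test_that("slope-difference identity holds to 1e-12 and WT self-coefficient is exactly 0", {
  set.seed(42)
  times <- c(0, 24, 48, 72)
  for (i in 1:20) {
    f_v <- runif(4, 0.01, 0.5)
    f_wt <- runif(4, 0.01, 0.5)
    s_joint <- selection_coefficient(f_v, f_wt, times)$s
    s_sep <- selection_coefficient(f_v, rep(0.25, 4), times)$s -
             selection_coefficient(f_wt, rep(0.25, 4), times)$s
    expect_equal(s_joint, s_sep, tolerance = 1e-12)
  }
  m <- matrix(rpois(9, 100), 3, 3, dimnames = list(c("a", "b", "WT"), NULL))
  fit <- fit_selection(to_frequencies(m), c(0, 24, 48), wt = "WT")
  expect_identical(fit$s[fit$genotype == "WT"], 0)
})

test_that("rescaling time by a rescales s by 1/a", {
  set.seed(5)
  times <- c(0, 24, 48, 72)
  f_v <- runif(4, 0.05, 0.4); f_wt <- runif(4, 0.05, 0.4)
  s1 <- selection_coefficient(f_v, f_wt, times)$s
  s2 <- selection_coefficient(f_v, f_wt, times * 3)$s
  expect_equal(s2, s1 / 3, tolerance = 1e-12)
})

test_that("log2 fold change vs t0 is WT-normalized, zero-anchored, and slope-consistent", {
  set.seed(9)
  m <- matrix(rpois(20, 200), 5, 4,
              dimnames = list(c(paste0("v", 1:4), "WT"), NULL))
  freqs <- to_frequencies(m)
  L <- log2fc_vs_t0(freqs, wt = "WT")
  expect_equal(unname(L[, 1]), rep(0, 5))
  expect_equal(unname(L["WT", ]), rep(0, 4))
  # constant frequencies give all zeros
  cf <- matrix(0.25, 4, 3, dimnames = list(c("a", "b", "c", "WT"), NULL))
  expect_equal(unname(log2fc_vs_t0(cf, wt = "WT")), matrix(0, 4, 3))
  # slope of each row equals the selection coefficient (algebraic identity)
  times <- c(0, 24, 48, 72)
  fit <- fit_selection(freqs, times, wt = "WT")
  for (g in rownames(freqs)) {
    slope <- unname(coef(lm(L[g, ] ~ times))[2])
    expect_equal(slope, fit$s[fit$genotype == g], tolerance = 1e-10)
  }
})

test_that("pairwise selection from fractions matches the log2-odds definition", {
  times <- c(0, 24, 48, 72, 96)
  expect_equal(pairwise_selection(times, rep(0.5, 5))$s, 0)
  # p chosen so log2 odds = t/24
  lambda <- times / 24
  p <- 2^lambda / (1 + 2^lambda)
  expect_equal(pairwise_selection(times, p)$s, 1 / 24, tolerance = 1e-12)
  # clamping handles degenerate 0/1 fractions without crashing
  est <- pairwise_selection(c(0, 24), c(0, 1), events = 10L)
  expect_true(is.finite(est$s))
  expect_error(pairwise_selection(c(0, 0), c(0.4, 0.5)), "increasing")
})

test_that("replicate aggregation is a symmetric mean/sd", {
  a <- aggregate_replicates(0.1)
  expect_equal(a$mean, 0.1); expect_equal(a$sd, 0)
  expect_equal(aggregate_replicates(c(0, 0.2))$mean, 0.1)
  x <- c(0.03, -0.01, 0.05, 0.02)
  expect_equal(aggregate_replicates(x)[c("mean", "sd")],
               aggregate_replicates(rev(x))[c("mean", "sd")])
  expect_error(aggregate_replicates(numeric(0)), "replicate")
})

test_that("condition correlation matches the textbook covariance formula", {
  a <- c(1, 2, 3, 4, 5); b <- c(2, 1, 4, 3, 5)
  # independent oracle: covariance over product of standard deviations
  oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(condition_correlation(a, b), oracle, tolerance = 1e-12)
  expect_equal(condition_correlation(a, a), 1)
  expect_equal(condition_correlation(a, -a), -1)
  expect_error(condition_correlation(a, rep(1, 5)), "variance")
  expect_error(condition_correlation(1:2, 1:2), "length")
})

test_that("planted selection coefficients are recovered from a small pooled screen", {
  # scaled-down screen: 32 genotypes + WT, depth 2e4, 3 replicates
  set.seed(NULL)
  genos <- enumerate_library(make_sites(5), library_scheme("A/E"))
  s_true <- setNames(seq(-0.04, 0.04, length.out = length(genos)), genos)
  sim <- simulate_pooled_screen(s_true, depth = 2e4, replicates = 3L,
                                seed = 101)
  est <- sapply(sim, function(rep) {
    freqs <- to_frequencies(rep$counts)
    fit <- fit_selection(freqs, rep$times, wt = "WT")
    setNames(fit$s, fit$genotype)
  })
  mean_est <- rowMeans(est)[genos]
  expect_gt(cor(mean_est, s_true[genos]), 0.95)
})
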