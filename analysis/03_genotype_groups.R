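#!/usr/bin/env Rscript
# Genotype-resolved summaries of the screen: selection coefficients grouped
# by phosphomimetic mutation count, per-site contrasts, and the
# Cks1-priming-site subset contrast in a WT/E library where mutants carrying
# phosphomimetic (EE) priming sites pay a planted cost under stress.

suppressPackageStartupMessages(library(phosscan))

outdir <- "results/genotype_groups"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
sites <- hcm1_tad_sites()

## A/E screen estimates from step 02
sel <- read.delim("results/screen_fitness/selection_licl.tsv")
sel <- sel[sel$genotype != "WT", ]
est <- data.frame(genotype = sel$genotype, s = sel$mean_s)
scheme_ae <- library_scheme("A/E")

grp <- group_by_count(est, scheme_ae, state = "E")
grp_df <- do.call(rbind, lapply(grp, function(g)
  data.frame(n_E = g$key, n = g$n, median = g$median, q25 = g$q25,
             q75 = g$q75)))
write.table(grp_df, file.path(outdir, "groups_by_nE_licl.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("median s by phosphomimetic count (LiCl):\n")
print(grp_df[, c("n_E", "n", "median")], row.names = FALSE)

## per-site contrasts in the A/E library
site_rows <- lapply(sites$label, function(lb) {
  ct <- site_contrast(est, lb, sites, scheme_ae)
  data.frame(site = lb, median_low = ct$low$median,
             median_high = ct$high$median,
             delta = ct$high$median - ct$low$median)
})
site_df <- do.call(rbind, site_rows)
write.table(site_df, file.path(outdir, "site_contrasts_licl.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

## WT/E library with a planted priming-site penalty under stress:
## mutants phosphomimetic at both T428 and T440 lose 0.01/h
scheme_we <- library_scheme("WT/E")
genos_we <- enumerate_library(sites, scheme_we)
states <- do.call(rbind, strsplit(genos_we, ""))
pen <- -0.01 * (states[, 1] == "E" & states[, 2] == "E")
s_we <- setNames(-0.005 + pen, genos_we)
sim <- simulate_pooled_screen(s_we, depth = 1e5, replicates = 4L,
                              seed = 20260301L)
est_we_mat <- sapply(sim, function(rep) {
  fit <- fit_selection(to_frequencies(rep$counts), rep$times, wt = "WT")
  setNames(fit$s, fit$genotype)
})
est_we <- data.frame(genotype = genos_we,
                     s = rowMeans(est_we_mat)[genos_we])
ct <- subset_contrast(est_we,
                      constraints_A = c(T428 = "E", T440 = "E"),
                      constraints_B = c(T428 = "W", T440 = "W"),
                      sites)
tst <- contrast_test(ct$values_A, ct$values_B, method = "mann-whitney")
cat(sprintf("\npriming-site subset contrast (WT/E, LiCl-like penalty):\n"))
cat(sprintf("  EE at T428+T440 (n=%d): median s = %.4f\n", ct$A$n, ct$A$median))
cat(sprintf("  WT at T428+T440 (n=%d): median s = %.4f\n", ct$B$n, ct$B$median))
cat(sprintf("  Mann-Whitney p = %.3g\n", tst$p_value))
write.table(data.frame(group = c("EE_T428_T440", "WT_T428_T440"),
                       n = c(ct$A$n, ct$B$n),
                       median = c(ct$A$median, ct$B$median),
                       mw_p = tst$p_value),
            file.path(outdir, "priming_subset_contrast.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

## deterministic heatmap ordering of the A/E library by (n_E, final log2FC)
manifest <- read.delim("results/screen_sim/manifest.tsv")
mc <- manifest[manifest$condition == "control" & manifest$replicate == 1, ]
mc <- mc[order(mc$hours), ]
cnt <- sapply(mc$file, function(f) {
  tb <- read_count_table(f); setNames(tb$counts$count, tb$counts$genotype)
})
L <- log2fc_vs_t0(to_frequencies(cnt), wt = "WT")
ord <- heatmap_order(L[rownames(L) != "WT", ], est$genotype)
writeLines(ord, file.path(outdir, "heatmap_order_control.txt"))
cat(sprintf("\nheatmap order: %s ... %s (%d genotypes)\n", ord[1],
            ord[length(ord)], length(ord)))
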