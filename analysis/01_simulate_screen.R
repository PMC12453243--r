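#!/usr/bin/env Rscript
# Simulate pooled phosphosite-scanning screens of the 256-mutant A/E library
# (+ WT spike-in) in control and LiCl-stress conditions, and write the
# per-timepoint count tables plus run manifests that the downstream fitness
# step consumes.
#
# Study geometry: 256 genotypes + WT, sampling every 24 h for 72 h, 4
# biological replicates, 1e5 reads per timepoint. Planted fitness model:
# in control medium phosphomimetic (E) sites add activity and a small
# additive benefit; under LiCl every fixed-phosphorylation-state mutant pays
# a fitness cost relative to WT, largest for the fully phosphomimetic
# mutant that can no longer be switched off.

suppressPackageStartupMessages(library(phosscan))

seed <- 20260101L
outdir <- "results/screen_sim"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

sites <- hcm1_tad_sites()
scheme <- library_scheme("A/E")
genos <- enumerate_library(sites, scheme)
n_E <- genotype_metrics(genos)$n_E

s_control <- setNames(0.002 * (n_E - 4), genos)         # -0.008 .. +0.008 /h
s_licl    <- setNames(-0.012 - 0.001 * n_E, genos)      # all mutants less fit

write_condition <- function(s_true, condition, seed) {
  sim <- simulate_pooled_screen(s_true, times = c(0, 24, 48, 72), depth = 1e5,
                                replicates = 4L, seed = seed)
  rows <- list()
  for (rep in sim) for (j in seq_along(rep$times)) {
    ct <- structure(list(
      counts = data.frame(genotype = rownames(rep$counts),
                          count = rep$counts[, j]),
      unassigned = 0L, ambiguous = 0L, total = sum(rep$counts[, j]),
      metadata = list()), class = "count_table")
    f <- file.path(outdir, sprintf("%s_rep%d_t%02d.tsv", condition,
                                   rep$replicate, rep$times[j]))
    write_count_table(ct, f)
    rows[[length(rows) + 1L]] <- data.frame(
      file = f, condition = condition, replicate = rep$replicate,
      hours = rep$times[j], role = "counts")
  }
  do.call(rbind, rows)
}

manifest <- rbind(write_condition(s_control, "control", seed),
                  write_condition(s_licl, "licl", seed + 1L))
write.table(manifest, file.path(outdir, "manifest.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(genotype = genos, s_control = s_control,
                       s_licl = s_licl),
            file.path(outdir, "planted_s.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("simulated %d genotypes + WT, 2 conditions x 4 replicates x 4 timepoints\n",
            length(genos)))
cat("manifest:", file.path(outdir, "manifest.tsv"), "\n")
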