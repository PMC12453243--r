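# shared fixtures: small site tables, templates and variant tables built in
# code at test time

make_sites <- function(n) {
  data.frame(ordinal = seq_len(n),
             label = paste0("T", 400 + 10 * seq_len(n)),
             wt_residue = rep("T", n),
             stringsAsFactors = FALSE)
}

# full synthetic variant table over n sites; read 1 covers the first half of
# the sites, read 2 the second half (n = 1 puts the single site in both)
make_variant_table <- function(n, scheme = library_scheme("A/E")) {
  sites <- make_sites(n)
  tpl <- synthetic_template(sites)
  len <- nchar(tpl$template)
  split_at <- if (n == 1L) len else tpl$codon_start[ceiling(n / 2) + 1L] - 2L
  r2_start <- if (n == 1L) 1L else split_at + 1L
  vt <- build_variant_table(sites, scheme, tpl$template, tpl$codon_start,
                            read_windows = list(r1 = c(1L, split_at),
                                                r2 = c(r2_start, len)))
  list(sites = sites, scheme = scheme, template = tpl, table = vt)
}

# write a simulated screen to per-timepoint count TSVs plus a manifest
write_screen_fixture <- function(dir, s_true, depth = 2e4, replicates = 2,
                                 seed = 50, condition = "control") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_pooled_screen(s_true, depth = depth,
                                replicates = replicates, seed = seed)
  rows <- list()
  for (rep in sim) {
    for (j in seq_along(rep$times)) {
      ct <- structure(list(
        counts = data.frame(genotype = rownames(rep$counts),
                            count = rep$counts[, j]),
        unassigned = 0L, ambiguous = 0L, total = sum(rep$counts[, j]),
        metadata = list()), class = "count_table")
      f <- file.path(dir, sprintf("%s_rep%d_t%d.tsv", condition,
                                  rep$replicate, rep$times[j]))
      write_count_table(ct, f)
      rows[[length(rows) + 1L]] <- data.frame(
        file = f, condition = condition, replicate = rep$replicate,
        hours = rep$times[j], role = "counts", stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# default 8-site A/E fixture used across files (built once per test run)
fx8 <- local({
  sites <- hcm1_tad_sites()
  scheme <- library_scheme("A/E")
  list(sites = sites, scheme = scheme,
       genotypes = enumerate_library(sites, scheme))
})
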