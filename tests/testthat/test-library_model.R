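test_that("library enumeration yields 2^n unique genotypes in deterministic order", {
  for (n in c(1, 2, 4, 8, 10)) {
    g <- enumerate_library(make_sites(n), library_scheme("A/E"))
    expect_length(g, 2^n)
    expect_equal(length(unique(g)), 2^n)
    expect_equal(g[1], strrep("A", n))          # all-low first
    expect_equal(g[2^n], strrep("E", n))        # all-high last
  }
  # ordinal 1 most significant, low before high
  g2 <- enumerate_library(make_sites(2), library_scheme("WT/E"))
  expect_equal(g2, c("WW", "WE", "EW", "EE"))
  # the 8-site A/E library of the TAD model
  expect_length(fx8$genotypes, 256)
})

test_that("mutation-count strata have binomial sizes", {
  m <- genotype_metrics(fx8$genotypes)
  for (k in 0:8)
    expect_equal(sum(m$n_E == k), choose(8, k))
  expect_equal(sum(table(m$n_E)), 256)
})

test_that("genotype metrics tally states and reject bad characters", {
  m <- genotype_metrics(c("EEEEEEEE", "WWWWWWWW", "AEWWAEWW"))
  expect_equal(m$n_E, c(8, 0, 2))
  expect_equal(m$n_W, c(0, 8, 4))
  expect_equal(m$n_A, c(0, 0, 2))
  expect_equal(m$n_W + m$n_A + m$n_E, rep(8L, 3))
  expect_error(genotype_metrics("AEXW"), "outside")
})

test_that("scheme state pairs and site-table validation follow the model", {
  expect_equal(library_scheme("A/E")[c("low_state", "high_state")],
               list(low_state = "A", high_state = "E"))
  expect_equal(library_scheme("WT/A")[c("low_state", "high_state")],
               list(low_state = "A", high_state = "W"))
  expect_equal(library_scheme("WT/E")[c("low_state", "high_state")],
               list(low_state = "W", high_state = "E"))
  expect_error(enumerate_library(make_sites(0), library_scheme("A/E")))
  bad <- make_sites(3); bad$label <- c("T430", "T420", "T440")
  expect_error(validate_sites(bad), "increase")
  bad2 <- make_sites(2); bad2$wt_residue <- c("T", "Y")
  expect_error(validate_sites(bad2), "S' or 'T")
})

test_that("default TAD site table has 8 sites with the published labels", {
  expect_equal(nrow(fx8$sites), 8)
  expect_true(all(c("T428", "T440", "T447", "T460", "S471", "T479", "T486")
                  %in% fx8$sites$label))
})

test_that("named mutants carry the documented substitutions", {
  nm <- named_mutants()
  s3 <- nm$substitutions[[which(nm$name == "hcm1-3S")]]
  expect_equal(s3, c(T428 = "S", T440 = "S", T447 = "S"))
  expect_equal(nm$n_substitutions[nm$name == "hcm1-3N"], 3L)
  expect_true(all(nm$substitutions[[which(nm$name == "hcm1-3N")]] == "A"))
  expect_true(nm$degron_stabilized[nm$name == "hcm1-3N8E"])
  expect_true(nm$tad_fixed[nm$name == "hcm1-8E"])
})

test_that("variant table encodes W/A/E codon replacements against the template", {
  fx <- make_variant_table(3)
  tpl <- fx$template
  len <- nchar(tpl$template)
  wt_row <- fx$table[fx$table$genotype == "WWW", ]
  sch_wt <- library_scheme("WT/E")
  vt_wt <- build_variant_table(fx$sites, sch_wt, tpl$template,
                               tpl$codon_start,
                               read_windows = list(r1 = c(1, len %/% 2),
                                                   r2 = c(len %/% 2 + 1, len)))
  # all-W genotype: expected sequences equal the unmodified template windows
  w_row <- vt_wt[vt_wt$genotype == "WWW", ]
  expect_equal(w_row$expected_read1, substr(tpl$template, 1, len %/% 2))
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  expect_equal(w_row$expected_read2,
               rc(substr(tpl$template, len %/% 2 + 1, len)))
  ndiff <- function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  # single-site E differs from WT in <= 6 nt within two adjacent codons
  for (g in c("EWW", "WEW", "WWE")) {
    row <- vt_wt[vt_wt$genotype == g, ]
    d <- ndiff(paste0(row$expected_read1, row$expected_read2),
               paste0(w_row$expected_read1, w_row$expected_read2))
    expect_lte(d, 6)
    expect_gt(d, 0)
  }
  # single-site A differs from WT in <= 3 nt (one codon)
  sch_wa <- library_scheme("WT/A")
  vt_wa <- build_variant_table(fx$sites, sch_wa, tpl$template,
                               tpl$codon_start,
                               read_windows = list(r1 = c(1, len %/% 2),
                                                   r2 = c(len %/% 2 + 1, len)))
  w2 <- vt_wa[vt_wa$genotype == "WWW", ]
  for (g in c("AWW", "WAW", "WWA")) {
    row <- vt_wa[vt_wa$genotype == g, ]
    d <- ndiff(paste0(row$expected_read1, row$expected_read2),
               paste0(w2$expected_read1, w2$expected_read2))
    expect_lte(d, 3)
    expect_gt(d, 0)
  }
})

test_that("expected sequence pairs are pairwise distinct (brute force, small n)", {
  for (n in 2:4) {
    vt <- make_variant_table(n)$table
    pairs <- paste(vt$expected_read1, vt$expected_read2)
    for (i in seq_along(pairs))
      for (j in seq_len(i - 1L))
        expect_false(pairs[i] == pairs[j])
  }
})

test_that("windows not covering a mutated site are rejected via uniqueness", {
  sites <- make_sites(2)
  tpl <- synthetic_template(sites)
  len <- nchar(tpl$template)
  # r1 and r2 both restricted to site-1's neighborhood: site-2 states collide
  expect_error(
    build_variant_table(sites, library_scheme("A/E"), tpl$template,
                        tpl$codon_start,
                        read_windows = list(r1 = c(1, 16), r2 = c(1, 16))),
    "unique")
  expect_error(
    build_variant_table(sites, library_scheme("A/E"), tpl$template,
                        tpl$codon_start,
                        read_windows = list(r1 = c(1, len + 5), r2 = c(1, len))),
    "bounds|window")
})

test_that("variant table TSV round-trips", {
  vt <- make_variant_table(2)$table
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(vt, path)
  expect_equal(read_variant_table(path), vt)
})
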