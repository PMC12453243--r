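#' Default TAD phosphosite table
#'
#' The transactivation domain (TAD) of the S-phase transcription factor Hcm1
#' carries eight CDK phosphosites. Seven have published residue coordinates
#' (T428, T440, T447, T460, S471, T479, T486); the eighth is represented by a
#' configurable placeholder label rather than an invented residue number.
#'
#' @param site8_label label for the eighth site (default `"site8"`).
#' @param site8_wt wild-type residue of the eighth site, `"S"` or `"T"`.
#' @return data.frame with columns `ordinal`, `label`, `wt_residue`, ordered
#'   N-terminal to C-terminal.
#' @export
hcm1_tad_sites <- function(site8_label = "site8", site8_wt = "T") {
  sites <- data.frame(
    ordinal    = 1:8,
    label      = c("T428", "T440", "T447", "T460", "S471", "T479", "T486",
                   site8_label),
    wt_residue = c("T", "T", "T", "T", "S", "T", "T", site8_wt),
    stringsAsFactors = FALSE
  )
  validate_sites(sites)
  sites
}

#' Validate a phosphosite table
#'
#' Checks label uniqueness, wild-type residues in \{S, T\}, and that residue
#' positions parsed from labels of the form `[ST]<number>` increase with the
#' N-to-C ordinal. Labels that do not encode a position (placeholders) are
#' exempt from the position check.
#'
#' @param sites data.frame with columns `ordinal`, `label`, `wt_residue`.
#' @return the validated table, invisibly.
#' @export
validate_sites <- function(sites) {
  stopifnot(is.data.frame(sites),
            all(c("ordinal", "label", "wt_residue") %in% names(sites)))
  if (nrow(sites) < 1L)
    stop("site table is empty", call. = FALSE)
  if (anyDuplicated(sites$label))
    stop("site labels must be unique", call. = FALSE)
  if (!all(sites$wt_residue %in% c("S", "T")))
    stop("wt_residue must be 'S' or 'T'", call. = FALSE)
  if (!identical(sites$ordinal, seq_len(nrow(sites))))
    stop("ordinals must be 1..n in order", call. = FALSE)
  parseable <- grepl("^[ST][0-9]+$", sites$label)
  pos <- suppressWarnings(as.integer(sub("^[ST]", "", sites$label[parseable])))
  if (any(diff(pos) <= 0))
    stop("residue positions must strictly increase with ordinal", call. = FALSE)
  invisible(sites)
}

#' Two-state library scheme
#'
#' A combinatorial phosphomutant library assigns one of two states to every
#' site: phosphodead alanine (`A`), phosphomimetic glutamate pair (`E`), or
#' wild type (`W`). The three schemes used in phosphosite scanning are `A/E`
#' (every site A or E), `WT/A`, and `WT/E`. `low_state` precedes `high_state`
#' in the enumeration order.
#'
#' @param name one of `"A/E"`, `"WT/A"`, `"WT/E"`.
#' @return list with elements `name`, `low_state`, `high_state`.
#' @export
library_scheme <- function(name = c("A/E", "WT/A", "WT/E")) {
  name <- match.arg(name)
  states <- switch(name,
    "A/E"  = c("A", "E"),
    "WT/A" = c("A", "W"),
    "WT/E" = c("W", "E")
  )
  structure(list(name = name, low_state = states[1L], high_state = states[2L]),
            class = "phosscan_scheme")
}

#' Enumerate a combinatorial mutant library
#'
#' Generates all 2^n genotypes of a two-state scheme over `n` sites, as state
#' strings over \{W, A, E\} read N-terminal to C-terminal. Order is
#' deterministic lexicographic: the low state sorts before the high state and
#' site 1 is the most significant position, so the all-low genotype comes
#' first and the all-high genotype last.
#'
#' @param sites site table (see [hcm1_tad_sites()]).
#' @param scheme a [library_scheme()].
#' @return character vector of 2^n unique genotype strings.
#' @export
#' @examples
#' length(enumerate_library(hcm1_tad_sites(), library_scheme("A/E")))  # 256
enumerate_library <- function(sites, scheme) {
  validate_sites(sites)
  if (!inherits(scheme, "phosscan_scheme"))
    stop("scheme must be built with library_scheme()", call. = FALSE)
  n <- nrow(sites)
  states <- c(scheme$low_state, scheme$high_state)
  # expand.grid varies the first factor fastest; feed sites in reverse so that
  # ordinal 1 is most significant, then reassemble columns N-to-C
  grid <- expand.grid(rep(list(states), n), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid <- grid[, rev(seq_len(n)), drop = FALSE]
  genotypes <- do.call(paste0, grid)
  stopifnot(!anyDuplicated(genotypes))
  genotypes
}

#' Per-genotype state counts
#'
#' Tallies wild-type (`W`), phosphodead (`A`) and phosphomimetic (`E`) sites
#' in each genotype string.
#'
#' @param genotypes character vector of state strings over \{W, A, E\}.
#' @return data.frame with columns `genotype`, `n_W`, `n_A`, `n_E`.
#' @export
genotype_metrics <- function(genotypes) {
  chars <- strsplit(genotypes, "", fixed = TRUE)
  bad <- vapply(chars, function(x) any(!x %in% c("W", "A", "E")), logical(1))
  if (any(bad))
    stop("genotype contains characters outside {W, A, E}: ",
         paste(genotypes[bad], collapse = ", "), call. = FALSE)
  count_state <- function(s) vapply(chars, function(x) sum(x == s), integer(1))
  data.frame(genotype = genotypes,
             n_W = count_state("W"),
             n_A = count_state("A"),
             n_E = count_state("E"),
             stringsAsFactors = FALSE)
}

#' Named point mutants used in pairwise assays
#'
#' Annotations for the named mutants that sit outside the two-state library
#' schemes: `hcm1-3S` (Cks1-priming sites T428, T440, T447 mutated to serine,
#' which CDK still phosphorylates but Cks1 cannot dock on), `hcm1-3N` (three
#' alanine substitutions in the N-terminal phosphodegron, stabilizing the
#' protein), `hcm1-8E` (all eight TAD sites phosphomimetic), and `hcm1-3N8E`
#' (both combined).
#'
#' @return data.frame with columns `name`, `n_substitutions`, `tad_fixed`,
#'   `degron_stabilized`, and a list-column `substitutions` of
#'   site-label -> replacement maps.
#' @export
named_mutants <- function() {
  subs <- list(
    "hcm1-3S"   = c(T428 = "S", T440 = "S", T447 = "S"),
    "hcm1-3N"   = c(degron1 = "A", degron2 = "A", degron3 = "A"),
    "hcm1-8E"   = c(T428 = "EE", T440 = "EE", T447 = "EE", T460 = "EE",
                    S471 = "EE", T479 = "EE", T486 = "EE", site8 = "EE"),
    "hcm1-3N8E" = c(degron1 = "A", degron2 = "A", degron3 = "A",
                    T428 = "EE", T440 = "EE", T447 = "EE", T460 = "EE",
                    S471 = "EE", T479 = "EE", T486 = "EE", site8 = "EE")
  )
  out <- data.frame(
    name = names(subs),
    n_substitutions = lengths(subs),
    tad_fixed = c(FALSE, FALSE, TRUE, TRUE),
    degron_stabilized = c(FALSE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out$substitutions <- unname(subs)
  out
}

#' Synthetic amplicon template for a site table
#'
#' Builds a synthetic DNA template carrying one wild-type S/T codon followed
#' by a proline codon per site, separated by fixed spacer sequence. This is a
#' stand-in amplicon for simulation and testing — the real library's
#' nucleotide sequence is supplied by the user as configuration.
#'
#' @param sites site table.
#' @param spacer_len spacer length (nt) between consecutive site dipeptides
#'   and at both ends.
#' @return list with `template` (DNA string) and `codon_start` (1-based start
#'   of each site's S/T codon).
#' @export
synthetic_template <- function(sites, spacer_len = 9L) {
  validate_sites(sites)
  wt_codon <- c(S = "TCT", T = "ACT")
  pro <- "CCA"
  # deterministic spacer: cycle through a fixed 4-mer
  spacer <- function(len) {
    paste(rep_len(strsplit("GATC", "")[[1]], len), collapse = "")
  }
  parts <- character(0)
  codon_start <- integer(nrow(sites))
  pos <- 0L
  for (i in seq_len(nrow(sites))) {
    sp <- spacer(spacer_len)
    parts <- c(parts, sp)
    pos <- pos + spacer_len
    codon_start[i] <- pos + 1L
    parts <- c(parts, wt_codon[[sites$wt_residue[i]]], pro)
    pos <- pos + 6L
  }
  parts <- c(parts, spacer(spacer_len))
  list(template = paste(parts, collapse = ""), codon_start = codon_start)
}

#' Build the expected-sequence table for exact-match read counting
#'
#' For each genotype of the scheme library, applies the per-site codon
#' replacements to the template (alanine replaces the S/T codon, 3 nt; the
#' glutamate pair replaces the S/T-P dipeptide codons, 6 nt; wild-type sites
#' are untouched), then extracts the read-1 window from the forward strand
#' and the read-2 window as the reverse complement of the template window.
#'
#' @param sites site table.
#' @param scheme a [library_scheme()].
#' @param template DNA string covering all site codons.
#' @param codon_start 1-based start position of each site's S/T codon in the
#'   template.
#' @param read_windows list with numeric `r1 = c(start, end)` and
#'   `r2 = c(start, end)` giving template coordinates of the two read windows.
#' @param codon_map list with elements `A` (3-nt alanine codon) and `E`
#'   (6-nt glutamate-pair codons); defaults GCT / GAAGAA.
#' @return data.frame with columns `genotype`, `expected_read1`,
#'   `expected_read2`; the sequence pairs are unique across the library.
#' @export
build_variant_table <- function(sites, scheme, template, codon_start,
                                read_windows,
                                codon_map = list(A = "GCT", E = "GAAGAA")) {
  validate_sites(sites)
  n <- nrow(sites)
  stopifnot(length(codon_start) == n, nchar(codon_map$A) == 3L,
            nchar(codon_map$E) == 6L)
  tlen <- nchar(template)
  if (any(codon_start < 1L | codon_start + 5L > tlen))
    stop("template does not cover all site codons (S/T plus proline)",
         call. = FALSE)
  for (w in c("r1", "r2")) {
    win <- read_windows[[w]]
    if (is.null(win) || length(win) != 2L || win[1] < 1L || win[2] > tlen ||
        win[1] > win[2])
      stop("read window '", w, "' outside template bounds", call. = FALSE)
  }
  genotypes <- enumerate_library(sites, scheme)
  mutate_one <- function(g) {
    seq <- template
    states <- strsplit(g, "", fixed = TRUE)[[1]]
    for (i in seq_len(n)) {
      if (states[i] == "A") {
        substr(seq, codon_start[i], codon_start[i] + 2L) <- codon_map$A
      } else if (states[i] == "E") {
        substr(seq, codon_start[i], codon_start[i] + 5L) <- codon_map$E
      }
    }
    seq
  }
  mutated <- vapply(genotypes, mutate_one, character(1))
  r1 <- substr(mutated, read_windows$r1[1], read_windows$r1[2])
  r2win <- substr(mutated, read_windows$r2[1], read_windows$r2[2])
  r2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(r2win)))
  tab <- data.frame(genotype = genotypes, expected_read1 = unname(r1),
                    expected_read2 = unname(r2), stringsAsFactors = FALSE,
                    row.names = NULL)
  if (anyDuplicated(paste(tab$expected_read1, tab$expected_read2)))
    stop("expected sequence pairs are not unique across the library; ",
         "choose read windows that cover all mutated codons", call. = FALSE)
  tab
}

#' Read or write a variant table
#'
#' TSV with columns `genotype`, `expected_read1`, `expected_read2`.
#' @param path file path.
#' @param table variant table data.frame.
#' @return `read_variant_table` returns the data.frame; `write_variant_table`
#'   returns `path` invisibly.
#' @export
read_variant_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("genotype", "expected_read1", "expected_read2")
  if (!all(need %in% names(tab)))
    stop("variant table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  tab
}

#' @rdname read_variant_table
#' @export
write_variant_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
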