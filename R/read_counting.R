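#' Exact-match assignment of paired-end reads to library variants
#'
#' A read pair is assigned to a variant if and only if the variant's expected
#' read-1 sequence occurs as an exact substring of read 1 AND its expected
#' read-2 sequence occurs as an exact substring of read 2. Pairs matching no
#' variant are counted as unassigned; pairs matching more than one variant are
#' counted as ambiguous and excluded from the per-variant counts. No quality
#' filtering is applied: exact sequence identity is the only filter, and `N`
#' bases never match. Orientation is fixed by the table (read 1 against
#' `expected_read1`); swapped pairs are not rescued.
#'
#' @param r1,r2 character vectors of read sequences, paired by position.
#' @param table variant table with columns `genotype`, `expected_read1`,
#'   `expected_read2` (see [build_variant_table()]).
#' @param metadata optional named list (condition, replicate, hours) carried
#'   into the result.
#' @return object of class `count_table`: list with `counts` (data.frame
#'   `genotype`, `count`), `unassigned`, `ambiguous`, `total`, `metadata`.
#'   `assigned + unassigned + ambiguous == total` always holds.
#' @export
count_exact <- function(r1, r2, table, metadata = list()) {
  if (length(r1) != length(r2))
    stop("r1 and r2 differ in length: reads are not paired", call. = FALSE)
  key <- paste(table$expected_read1, table$expected_read2)
  if (anyDuplicated(key))
    stop("duplicate expected sequence pairs in variant table", call. = FALSE)
  n_reads <- length(r1)
  n_matches <- integer(n_reads)
  assigned_to <- integer(n_reads)
  for (v in seq_len(nrow(table))) {
    hit <- grepl(table$expected_read1[v], r1, fixed = TRUE) &
           grepl(table$expected_read2[v], r2, fixed = TRUE)
    n_matches[hit] <- n_matches[hit] + 1L
    assigned_to[hit] <- v
  }
  uniq <- n_matches == 1L
  counts <- tabulate(assigned_to[uniq], nbins = nrow(table))
  structure(list(
    counts = data.frame(genotype = table$genotype, count = counts,
                        stringsAsFactors = FALSE),
    unassigned = sum(n_matches == 0L),
    ambiguous = sum(n_matches > 1L),
    total = n_reads,
    metadata = metadata
  ), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", nrow(x$counts), "variants,", x$total, "pairs (",
      sum(x$counts$count), "assigned,", x$unassigned, "unassigned,",
      x$ambiguous, "ambiguous )\n")
  invisible(x)
}

#' Count variants directly from a paired FASTQ file
#'
#' Reads both mates (plain or gzipped FASTQ), pairs them by record order, and
#' runs [count_exact()].
#'
#' @param fastq_r1,fastq_r2 paths to the read-1 / read-2 FASTQ files.
#' @inheritParams count_exact
#' @return a `count_table` (see [count_exact()]).
#' @export
count_fastq_pair <- function(fastq_r1, fastq_r2, table, metadata = list()) {
  r1 <- as.character(Biostrings::readDNAStringSet(fastq_r1, format = "fastq"))
  r2 <- as.character(Biostrings::readDNAStringSet(fastq_r2, format = "fastq"))
  if (length(r1) != length(r2))
    stop("FASTQ files have different record counts: ", fastq_r1, " (",
         length(r1), ") vs ", fastq_r2, " (", length(r2), ")", call. = FALSE)
  count_exact(unname(r1), unname(r2), table, metadata = metadata)
}

#' Write a count table to TSV
#'
#' Emits one row per genotype plus `__unassigned__` and `__ambiguous__`
#' summary rows, so that the column total equals the number of pairs
#' processed.
#'
#' @param x a `count_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path) {
  stopifnot(inherits(x, "count_table"))
  out <- rbind(x$counts,
               data.frame(genotype = c("__unassigned__", "__ambiguous__"),
                          count = c(x$unassigned, x$ambiguous)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count table TSV written by [write_count_table()]
#'
#' @param path file path.
#' @param metadata optional metadata list.
#' @return a `count_table`.
#' @export
read_count_table <- function(path, metadata = list()) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("genotype", "count") %in% names(tab)))
    stop("count table must have columns genotype, count: ", path,
         call. = FALSE)
  special <- tab$genotype %in% c("__unassigned__", "__ambiguous__")
  unassigned <- sum(tab$count[tab$genotype == "__unassigned__"])
  ambiguous <- sum(tab$count[tab$genotype == "__ambiguous__"])
  counts <- tab[!special, , drop = FALSE]
  rownames(counts) <- NULL
  structure(list(counts = counts, unassigned = unassigned,
                 ambiguous = ambiguous,
                 total = sum(counts$count) + unassigned + ambiguous,
                 metadata = metadata),
            class = "count_table")
}
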