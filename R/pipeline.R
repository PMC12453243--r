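#' Validate a run manifest
#'
#' A manifest is a data.frame with columns `file`, `condition`, `replicate`,
#' `hours`, `role`; the (condition, replicate, hours, role) combinations must
#' be unique and every referenced file must exist.
#'
#' @param manifest manifest data.frame.
#' @param roles roles allowed in this run.
#' @return the manifest, invisibly.
#' @export
validate_manifest <- function(manifest,
                              roles = c("screen_r1", "screen_r2", "counts",
                                        "events", "control_events", "pixels",
                                        "traces", "growth")) {
  need <- c("file", "condition", "replicate", "hours", "role")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(manifest$role %in% roles))
    stop("unknown manifest role(s): ",
         paste(unique(setdiff(manifest$role, roles)), collapse = ", "),
         call. = FALSE)
  key <- paste(manifest$condition, manifest$replicate, manifest$hours,
               manifest$role)
  if (anyDuplicated(key))
    stop("duplicate (condition, replicate, hours, role) rows in manifest",
         call. = FALSE)
  missing <- !file.exists(manifest$file)
  if (any(missing))
    stop("manifest file(s) not found: ",
         paste(utils::head(manifest$file[missing], 5L), collapse = ", "),
         call. = FALSE)
  invisible(manifest)
}

# assemble one replicate's counts matrix (variants x hours) from manifest rows
.replicate_count_matrix <- function(rows, variant_table) {
  rows <- rows[order(rows$hours), , drop = FALSE]
  tabs <- lapply(seq_len(nrow(rows)), function(i) {
    if (rows$role[i] == "counts") {
      read_count_table(rows$file[i])
    } else {
      stop("screen FASTQ roles must be paired and pre-counted upstream; ",
           "use count_fastq_pair() and the 'counts' role", call. = FALSE)
    }
  })
  genos <- tabs[[1L]]$counts$genotype
  for (tb in tabs[-1L])
    if (!identical(tb$counts$genotype, genos))
      stop("inconsistent genotype sets across timepoints", call. = FALSE)
  counts <- vapply(tabs, function(tb) tb$counts$count, integer(length(genos)))
  dimnames(counts) <- list(genos, paste0("t", rows$hours))
  list(counts = counts, times = rows$hours)
}

#' Run the pooled-screen analysis end to end
#'
#' Composes counting, frequency normalization and selection-coefficient
#' estimation: for every (condition, replicate) the per-timepoint count
#' tables named in the manifest are assembled into a count matrix,
#' pseudocounted frequencies are computed, per-variant selection coefficients
#' are fitted against the WT reference, and replicate estimates are averaged
#' per condition. Writes one selection TSV per condition
#' (`selection_<condition>.tsv` with per-replicate columns, mean and sd), a
#' mutation-count group-summary TSV when `scheme` is supplied, and a
#' `run_report.txt` recording package version and parameters. All outputs are
#' deterministic functions of the inputs.
#'
#' @param manifest manifest data.frame (role `"counts"`; see
#'   [validate_manifest()]). FASTQ inputs are first converted with
#'   [count_fastq_pair()] / [write_count_table()].
#' @param outdir output directory (created if needed).
#' @param pseudocount forwarded to [to_frequencies()].
#' @param wt genotype name of the WT reference row.
#' @param scheme,sites optional [library_scheme()] and site table; when given
#'   and the genotype set covers the full library, group-by-count summaries
#'   are also written.
#' @return named list (per condition) of selection data.frames, invisibly.
#' @export
run_screen <- function(manifest, outdir, pseudocount = 0.5, wt = "WT",
                       scheme = NULL, sites = NULL) {
  validate_manifest(manifest, roles = "counts")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  for (cond in unique(manifest$condition)) {
    mc <- manifest[manifest$condition == cond, , drop = FALSE]
    per_rep <- list()
    for (rep_id in sort(unique(mc$replicate))) {
      mr <- mc[mc$replicate == rep_id, , drop = FALSE]
      if (length(unique(mr$hours)) < 2L)
        stop("condition ", cond, " replicate ", rep_id,
             " has fewer than 2 timepoints", call. = FALSE)
      cm <- .replicate_count_matrix(mr, NULL)
      if (!0 %in% cm$times)
        stop("t0 = 0 timepoint missing for condition ", cond, " replicate ",
             rep_id, call. = FALSE)
      if (!wt %in% rownames(cm$counts))
        stop("WT reference '", wt, "' missing from counts", call. = FALSE)
      freqs <- to_frequencies(cm$counts, pseudocount = pseudocount)
      per_rep[[as.character(rep_id)]] <- fit_selection(freqs, cm$times,
                                                       wt = wt)
    }
    genos <- per_rep[[1L]]$genotype
    smat <- vapply(per_rep, function(d) d$s, numeric(length(genos)))
    smat <- matrix(smat, nrow = length(genos),
                   dimnames = list(genos, paste0("s_rep", names(per_rep))))
    sel <- data.frame(genotype = genos, condition = cond,
                      mean_s = rowMeans(smat),
                      sd_s = apply(smat, 1L, function(x)
                        if (length(x) > 1L) stats::sd(x) else 0),
                      smat, row.names = NULL, check.names = FALSE,
                      stringsAsFactors = FALSE)
    utils::write.table(sel, file.path(outdir,
                                      paste0("selection_", cond, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(scheme)) {
      lib <- sel[sel$genotype != wt, , drop = FALSE]
      grp <- group_by_count(data.frame(genotype = lib$genotype,
                                       s = lib$mean_s), scheme)
      utils::write.table(.summary_df(grp),
                         file.path(outdir, paste0("groups_nhigh_", cond,
                                                  ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    results[[cond]] <- sel
  }
  writeLines(c("phosscan screen run",
               paste0("package_version: ",
                      as.character(utils::packageVersion("phosscan"))),
               paste0("pseudocount: ", pseudocount),
               paste0("wt: ", wt),
               paste0("conditions: ",
                      paste(unique(manifest$condition), collapse = ","))),
             file.path(outdir, "run_report.txt"))
  invisible(results)
}

#' Run the pairwise-competition analysis end to end
#'
#' For every (condition, replicate) the per-timepoint event tables (sample
#' and non-fluorescent control) named in the manifest are gated with
#' [gfp_positive_fraction()] to give the mutant-fraction trajectory, the
#' log2-odds slope is fitted with [pairwise_selection()], and replicate
#' estimates are averaged per condition. Writes `pairwise_selection.tsv`.
#'
#' @param manifest manifest with roles `"events"` and `"control_events"`;
#'   event files are CSV with a `green` column.
#' @param outdir output directory.
#' @param events cytometry events per sample (clamp bound for the logit).
#' @return data.frame (condition, mean_s, sd_s, n_replicates), invisibly.
#' @export
run_pairwise <- function(manifest, outdir, events = 5000L) {
  validate_manifest(manifest, roles = c("events", "control_events"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (cond in unique(manifest$condition)) {
    mc <- manifest[manifest$condition == cond, , drop = FALSE]
    s_reps <- vapply(sort(unique(mc$replicate)), function(rep_id) {
      mr <- mc[mc$replicate == rep_id, , drop = FALSE]
      hrs <- sort(unique(mr$hours))
      frac <- vapply(hrs, function(h) {
        ev <- utils::read.csv(mr$file[mr$hours == h & mr$role == "events"])
        ct <- utils::read.csv(mr$file[mr$hours == h &
                                      mr$role == "control_events"])
        gfp_positive_fraction(ev$green, ct$green) / 100
      }, numeric(1))
      pairwise_selection(hrs, frac, events = events)$s
    }, numeric(1))
    agg <- aggregate_replicates(s_reps)
    rows[[cond]] <- data.frame(condition = cond, mean_s = agg$mean,
                               sd_s = agg$sd, n_replicates = agg$n,
                               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  utils::write.table(out, file.path(outdir, "pairwise_selection.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
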