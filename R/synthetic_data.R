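# run expr with a local RNG stream: set the seed, restore the caller's
# .Random.seed afterwards, so generators are bit-reproducible and do not
# perturb the session RNG
.with_seed <- function(seed, expr) {
  if (is.null(seed) || !is.finite(seed))
    stop("a seed is mandatory for every generator", call. = FALSE)
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = env)
    else assign(".Random.seed", old, envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

#' Simulate a pooled phosphosite-scanning screen
#'
#' Latent variant frequencies drift deterministically and exponentially,
#' `f_v(t) proportional to f_v(0) * 2^(s_v * t)` (renormalized each
#' timepoint), and the observed counts at each timepoint are one multinomial
#' draw of size `depth` from the latent frequencies — sequencing sampling
#' noise on top of deterministic selection. The WT reference has s = 0 by
#' construction. Population bottlenecks at dilution are not modeled.
#'
#' @param s named numeric vector of true selection coefficients (log2 units
#'   per hour), one per genotype; a `WT` entry is added with s = 0 if absent,
#'   and forced to 0 if present.
#' @param times timepoints in hours (default `c(0, 24, 48, 72)`: sampling
#'   every 24 h for 72 h).
#' @param depth reads per timepoint (multinomial size).
#' @param replicates number of biological replicates (default 4).
#' @param f0 initial frequencies (default uniform over variants).
#' @param seed RNG seed (mandatory); replicate r uses `seed + r - 1`.
#' @return list of replicates; each is a list with `counts` (variants x
#'   timepoints integer matrix, genotype rownames), `times`, `replicate`.
#'   The true `s` (with WT) is attached as attribute `"s_true"`.
#' @export
simulate_pooled_screen <- function(s, times = c(0, 24, 48, 72), depth = 1e5,
                                   replicates = 4L, f0 = NULL, seed) {
  if (is.null(names(s)) || anyDuplicated(names(s)))
    stop("s must be a uniquely named vector of per-genotype coefficients",
         call. = FALSE)
  if (!"WT" %in% names(s)) s <- c(s, WT = 0)
  s["WT"] <- 0
  n_v <- length(s)
  if (is.null(f0)) f0 <- rep(1 / n_v, n_v)
  if (length(f0) != n_v || abs(sum(f0) - 1) > 1e-8 || any(f0 <= 0))
    stop("f0 must be positive and sum to 1 over all variants", call. = FALSE)
  if (depth < 1) stop("depth must be >= 1", call. = FALSE)
  if (length(times) < 2L || any(diff(times) <= 0))
    stop("need >= 2 strictly increasing timepoints", call. = FALSE)
  latent <- vapply(times, function(t) {
    f <- f0 * 2^(s * t)
    f / sum(f)
  }, numeric(n_v))
  reps <- lapply(seq_len(replicates), function(r) {
    counts <- .with_seed(seed + r - 1L,
      vapply(seq_along(times),
             function(j) as.integer(stats::rmultinom(1L, depth, latent[, j])),
             integer(n_v)))
    dimnames(counts) <- list(names(s), paste0("t", times))
    list(counts = counts, times = times, replicate = r)
  })
  attr(reps, "s_true") <- s
  reps
}

#' Simulate error-bearing paired reads from a count table
#'
#' Emits exactly the requested number of read pairs per genotype. Each read
#' embeds the variant's expected sequence at a random offset, padded to the
#' read length with random flanking bases, then independent per-base
#' substitutions are applied at rate `error_rate` (a substituted base is
#' drawn uniformly from the three other bases, so it always differs).
#'
#' @param counts data.frame with columns `genotype`, `count`.
#' @param table variant table (see [build_variant_table()]).
#' @param error_rate per-base substitution probability in `[0, 1)`.
#' @param read_length read length in nt (must cover the expected sequences).
#' @param seed RNG seed (mandatory).
#' @return list with character vectors `r1`, `r2` and the emission order
#'   `genotype`; `length(r1) == sum(counts$count)`.
#' @export
simulate_read_pairs <- function(counts, table, error_rate = 0,
                                read_length = 150L, seed) {
  if (error_rate < 0 || error_rate >= 1)
    stop("error_rate must lie in [0, 1)", call. = FALSE)
  idx <- match(counts$genotype, table$genotype)
  if (anyNA(idx))
    stop("count table contains genotypes absent from the variant table",
         call. = FALSE)
  maxlen <- max(nchar(table$expected_read1), nchar(table$expected_read2))
  if (read_length < maxlen)
    stop("read length ", read_length, " shorter than expected sequence (",
         maxlen, " nt)", call. = FALSE)
  bases <- c("A", "C", "G", "T")
  .with_seed(seed, {
    genotype <- rep(counts$genotype, counts$count)
    exp1 <- rep(table$expected_read1[idx], counts$count)
    exp2 <- rep(table$expected_read2[idx], counts$count)
    embed <- function(core) {
      vapply(core, function(cs) {
        pad <- read_length - nchar(cs)
        if (pad == 0L) return(cs)
        off <- sample.int(pad + 1L, 1L) - 1L
        paste0(paste(sample(bases, off, replace = TRUE), collapse = ""),
               cs,
               paste(sample(bases, pad - off, replace = TRUE), collapse = ""))
      }, character(1), USE.NAMES = FALSE)
    }
    mutate <- function(reads) {
      if (error_rate == 0 || length(reads) == 0L) return(reads)
      mat <- do.call(rbind, strsplit(reads, "", fixed = TRUE))
      hit <- matrix(stats::runif(length(mat)) < error_rate, nrow = nrow(mat))
      if (any(hit)) {
        cur <- mat[hit]
        mat[hit] <- vapply(cur, function(b)
          sample(setdiff(bases, b), 1L), character(1))
      }
      apply(mat, 1L, paste, collapse = "")
    }
    list(r1 = mutate(embed(exp1)), r2 = mutate(embed(exp2)),
         genotype = genotype)
  })
}

#' Write a simulated read-pair set as paired FASTQ
#'
#' @param pairs list from [simulate_read_pairs()].
#' @param prefix output path prefix; writes `<prefix>_R1.fastq` and
#'   `<prefix>_R2.fastq` (add `.gz` via `compress`).
#' @param compress gzip the output files.
#' @return character vector of the two paths, invisibly.
#' @export
write_fastq_pair <- function(pairs, prefix, compress = FALSE) {
  ids <- sprintf("pair%06d", seq_along(pairs$r1))
  ext <- if (compress) ".fastq.gz" else ".fastq"
  paths <- paste0(prefix, c("_R1", "_R2"), ext)
  for (i in 1:2) {
    seqs <- Biostrings::DNAStringSet(pairs[[c("r1", "r2")[i]]])
    names(seqs) <- ids
    Biostrings::writeXStringSet(seqs, paths[i], format = "fastq",
                                compress = compress)
  }
  invisible(paths)
}

#' Simulate a pairwise co-culture competition trajectory
#'
#' The latent log2 odds of the mutant fraction evolves linearly with slope
#' `s`; the observed fraction at each timepoint is a binomial draw of
#' `events` cells at the latent fraction, divided by `events` — flow
#' cytometry counting noise.
#'
#' @param s true selection coefficient (log2 odds units per hour).
#' @param p0 initial mutant fraction in `(0, 1)` (default 0.5: equal
#'   mixing).
#' @param times timepoints in hours (default `c(0, 24, 48, 72, 96)`).
#' @param events cytometry events per timepoint (default 5000).
#' @param seed RNG seed (mandatory).
#' @return data.frame with columns `hours`, `fraction`.
#' @export
simulate_pairwise_flow <- function(s, p0 = 0.5, times = c(0, 24, 48, 72, 96),
                                   events = 5000L, seed) {
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie in (0, 1)", call. = FALSE)
  if (events < 1L) stop("events must be >= 1", call. = FALSE)
  lambda <- log2(p0 / (1 - p0)) + s * times
  p <- 2^lambda / (1 + 2^lambda)
  obs <- .with_seed(seed,
    stats::rbinom(length(times), events, p) / events)
  data.frame(hours = times, fraction = obs)
}

#' Simulate a green-fluorescence event table with a bright sub-population
#'
#' Mixture of a lognormal background (autofluorescence) and a lognormal
#' bright (GFP-expressing) component; each event is bright with probability
#' `pct_bright / 100`.
#'
#' @param pct_bright percentage of bright events in `[0, 100]`.
#' @param n number of events (default 5000).
#' @param bg_meanlog,bg_sdlog lognormal parameters of the background.
#' @param bright_meanlog,bright_sdlog lognormal parameters of the bright
#'   component.
#' @param seed RNG seed (mandatory).
#' @return data.frame with columns `green` and `bright` (the latent label).
#' @export
simulate_flow_events <- function(pct_bright, n = 5000L,
                                 bg_meanlog = log(100), bg_sdlog = 0.3,
                                 bright_meanlog = log(3000),
                                 bright_sdlog = 0.3, seed) {
  if (pct_bright < 0 || pct_bright > 100)
    stop("pct_bright must lie in [0, 100]", call. = FALSE)
  .with_seed(seed, {
    bright <- stats::runif(n) < pct_bright / 100
    green <- numeric(n)
    green[!bright] <- stats::rlnorm(sum(!bright), bg_meanlog, bg_sdlog)
    green[bright] <- stats::rlnorm(sum(bright), bright_meanlog, bright_sdlog)
    data.frame(green = green, bright = bright)
  })
}

#' Simulate a DNA-content histogram (1C / 2C peaks with an S-phase bridge)
#'
#' Gaussian peaks at the 1C and 2C positions (width set by a coefficient of
#' variation) in the G1 and G2/M proportions, plus a uniform bridge on
#' `(c1, c2)` for the S-phase proportion — the shape of a Sytox-stained
#' asynchronous budding-yeast culture.
#'
#' @param n number of events (default 5000).
#' @param c1,c2 1C and 2C peak positions (`c1 < c2`).
#' @param fractions length-3 vector `(G1, S, G2)` summing to 1 (default
#'   `c(0.60, 0.16, 0.24)`: an asynchronous log-phase culture with ~16% of
#'   cells in S-phase).
#' @param cv coefficient of variation of both peaks (default 0.05, typical
#'   of a well-stained yeast DNA histogram).
#' @param seed RNG seed (mandatory).
#' @return numeric vector of per-event DNA content.
#' @export
simulate_dna_content <- function(n = 5000L, c1 = 100, c2 = 200,
                                 fractions = c(0.60, 0.16, 0.24), cv = 0.05,
                                 seed) {
  if (c1 >= c2) stop("c1 must lie below c2", call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-8 || any(fractions < 0))
    stop("fractions (G1, S, G2) must be nonnegative and sum to 1",
         call. = FALSE)
  .with_seed(seed, {
    phase <- sample(1:3, n, replace = TRUE, prob = fractions)
    dna <- numeric(n)
    dna[phase == 1L] <- stats::rnorm(sum(phase == 1L), c1, cv * c1)
    dna[phase == 2L] <- stats::runif(sum(phase == 2L), c1, c2)
    dna[phase == 3L] <- stats::rnorm(sum(phase == 3L), c2, cv * c2)
    dna
  })
}

#' Simulate per-cell pixel-intensity tables
#'
#' Non-nuclear cells draw every pixel from one symmetric Gaussian background;
#' nuclear cells replace a share of their pixels with a brighter nuclear
#' component (mean = `enrichment` times the background mean), producing the
#' long upper tail the localization ratio detects.
#'
#' @param n_cells number of cells.
#' @param pixels_per_cell pixels per segmented cell (default 200).
#' @param nuclear_frac fraction of cells carrying the nuclear sub-population.
#' @param nuclear_share share of a nuclear cell's pixels that are nuclear
#'   (default 0.1).
#' @param enrichment nuclear/background mean intensity ratio (default 3).
#' @param bg_mean,bg_sd background Gaussian parameters.
#' @param seed RNG seed (mandatory).
#' @return list with `pixels` (long data.frame `cell_id`, `pixel_value`) and
#'   `truth` (data.frame `cell_id`, `nuclear`).
#' @export
simulate_cell_pixels <- function(n_cells, pixels_per_cell = 200L,
                                 nuclear_frac = 0.4, nuclear_share = 0.1,
                                 enrichment = 3, bg_mean = 100, bg_sd = 10,
                                 seed) {
  if (nuclear_frac < 0 || nuclear_frac > 1 ||
      nuclear_share < 0 || nuclear_share > 1)
    stop("fractions must lie in [0, 1]", call. = FALSE)
  .with_seed(seed, {
    nuclear <- stats::runif(n_cells) < nuclear_frac
    n_nuc_px <- round(nuclear_share * pixels_per_cell)
    cells <- lapply(seq_len(n_cells), function(i) {
      px <- stats::rnorm(pixels_per_cell, bg_mean, bg_sd)
      if (nuclear[i] && n_nuc_px > 0L)
        px[seq_len(n_nuc_px)] <- stats::rnorm(n_nuc_px,
                                              enrichment * bg_mean, bg_sd)
      data.frame(cell_id = sprintf("cell%04d", i), pixel_value = px,
                 stringsAsFactors = FALSE)
    })
    list(pixels = do.call(rbind, cells),
         truth = data.frame(cell_id = sprintf("cell%04d", seq_len(n_cells)),
                            nuclear = nuclear, stringsAsFactors = FALSE))
  })
}

#' Simulate localization-ratio traces with planted activity pulses
#'
#' Each cell's trace is a flat baseline plus iid Gaussian noise; during each
#' scheduled pulse the ratio is raised to `pulse_height` (plus the same
#' noise). Frame spacing defaults to 0.5 min over 30 min, the acquisition
#' cadence of the reporter time-lapse experiments.
#'
#' @param schedule named list: one entry per cell, each a data.frame with
#'   columns `start` and `duration_min` (pulse start time and duration in
#'   minutes, aligned to the frame grid); an empty data.frame means no
#'   pulses.
#' @param n_frames frames per trace (default 60).
#' @param dt frame interval in minutes (default 0.5).
#' @param baseline baseline ratio (default 0).
#' @param pulse_height ratio during a pulse (default 1.5).
#' @param noise_sd iid noise sd (default 0.05).
#' @param seed RNG seed (mandatory).
#' @return data.frame with columns `cell_id`, `time_min`, `ratio`.
#' @export
simulate_traces <- function(schedule, n_frames = 60L, dt = 0.5, baseline = 0,
                            pulse_height = 1.5, noise_sd = 0.05, seed) {
  times <- (seq_len(n_frames) - 1L) * dt
  .with_seed(seed, {
    out <- lapply(names(schedule), function(id) {
      r <- rep(baseline, n_frames)
      sch <- schedule[[id]]
      if (NROW(sch) > 0L) for (j in seq_len(nrow(sch))) {
        on <- times >= sch$start[j] &
              times < sch$start[j] + sch$duration_min[j]
        r[on] <- pulse_height
      }
      data.frame(cell_id = id, time_min = times,
                 ratio = r + stats::rnorm(n_frames, 0, noise_sd),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}
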