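---
title: "Methods: quantitative analysis of phosphosite-scanning fitness screens"
author: "phosscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative analysis of phosphosite-scanning fitness screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosscan)
```

# Scope and model system

phosscan implements the quantitative analysis behind phosphosite scanning:
pooled competitive-fitness screening of all combinatorial phosphosite
mutants of a multisite CDK substrate, here the budding-yeast S-phase
transcription factor Hcm1. The Hcm1 transactivation domain (TAD) carries
eight CDK sites; mutating each site to alanine (phosphodead, `A`) or to a
glutamate pair replacing the S/T-P dipeptide (phosphomimetic, `E`), in all
combinations, yields 2^8 = 256 mutants per two-state library (`A/E`,
`WT/A`, `WT/E`). Seven sites have published coordinates (T428, T440, T447,
T460, S471, T479, T486); the eighth is carried as a configurable
placeholder (`site8`) rather than an invented residue number. The named
point mutants used in pairwise assays (`hcm1-3S`, `hcm1-3N`, `hcm1-8E`,
`hcm1-3N8E`) sit outside the two-state schemes and are modeled as
annotations.

The package covers the whole measurement chain: genotype bookkeeping and
expected-sequence tables, exact-match read counting, selection-coefficient
estimation from pooled screens and pairwise co-cultures, genotype-resolved
group statistics, flow-cytometry quantification, and a quantile-skewness
statistic for nuclear-translocation reporters. Seeded generators emulate
every raw input with known ground truth, so each estimator is validated by
parameter recovery.

# Selection coefficients

## Pooled screens

Variant abundance is measured by sequencing at timepoints every 24 h for
72 h (default grid {0, 24, 48, 72} h). Counts are converted to read
fractions after adding a pseudocount of 0.5 to every cell — the log2
transform is otherwise undefined for variants that drop out of a
sample; 0.5 is the conventional half-count and its influence vanishes at
typical per-variant depths (~400 reads at depth 1e5 over 257 variants).
The selection coefficient of variant *v* is the ordinary-least-squares
slope of

$$y_v(t) = \log_2 f_v(t) - \log_2 f_{WT}(t)$$

against time in hours, where the spiked-in WT plasmid is the reference. The
subtraction makes the statistic invariant to the common normalization
(column sums cancel), so the WT self-coefficient is exactly zero and the
slope-difference identity
$\mathrm{slope}(y_v) = \mathrm{slope}(\log_2 f_v) - \mathrm{slope}(\log_2 f_{WT})$
holds to machine precision on a common grid. Units are log2 per hour
throughout ($s = 1/24$ /h means the relative abundance doubles per day);
time is never rescaled internally, so $s$ co-varies as $1/a$ under a time
rescaling by $a$. The fit includes t0, is unweighted, and reports r² for
diagnostics. Replicates (default 4) are fitted independently and averaged;
the replicate sd is reported alongside.

## Pairwise co-cultures

In a two-strain co-culture the mutant fraction $p(t)$ and the WT fraction
$1-p(t)$ share one denominator, so the log2 fold change of mutant relative
to WT reduces to the log2 odds $\log_2\!\big(p/(1-p)\big)$; the selection
coefficient is its OLS slope against time ({0, 24, 48, 72, 96} h by
default). Fractions come from GFP gating at 5000 events per sample, so a
fraction of exactly 0 or 1 is a censoring artifact of finite events, not a
true extinction; fractions are clamped to
$[1/(N{+}1),\ 1-1/(N{+}1)]$ before the logit. The Laplace-style bound was
chosen over $[1/N, 1-1/N]$ because it remains a non-empty interval for
every $N \ge 1$ while being indistinguishable at $N = 5000$.

# Read counting

A read pair is assigned to a variant exactly when the variant's expected
read-1 sequence occurs as an exact substring of read 1 and its expected
read-2 sequence as an exact substring of read 2. Substring containment
(rather than whole-read equality) is used because 150-bp reads can extend
beyond the variant window; exact identity is the only filter — no quality
values are consulted, and `N` bases never match. Pairs matching no variant
are reported unassigned; pairs matching more than one are reported
ambiguous and excluded, the conservative choice for a count statistic.
Orientation is fixed by the table; swapped pairs are not rescued. The
conservation law assigned + unassigned + ambiguous = total holds for every
input and is asserted in tests.

Expected sequences are built from a template and per-site codon map:
alanine replaces the S/T codon (3 nt, default `GCT`), the glutamate pair
replaces the S/T-P dipeptide (6 nt, default `GAAGAA`). Template, codon
map and read windows are configuration inputs for real data — the package
does not hard-code any particular amplicon;
`synthetic_template()` provides a clearly synthetic stand-in amplicon for
simulation and tests. Read windows must jointly cover every mutated codon —
`build_variant_table()` enforces this indirectly by refusing a table whose
expected-sequence pairs are not unique.

# Genotype-resolved statistics

Group summaries follow box-plot conventions: quantiles by linear
interpolation between order statistics (type 7 — the one convention used
everywhere in the package), whiskers at the most extreme points within
1.5 IQR of the quartiles, points beyond listed as outliers. Strata by
phosphomimetic count have binomial sizes $\binom{8}{k}$; per-site contrasts
split the library into halves of 128; subset contrasts select genotypes by
site-to-state constraint maps (e.g. `EE` at both Cks1-priming sites T428
and T440 versus `WT` there). Heatmap ordering is deterministic: primary key
number of `E` sites ascending, secondary key control-condition log2 fold
change at the final timepoint ascending, residual ties broken by genotype
string.

The default two-group test is the two-sided Mann-Whitney test, the robust
choice for 64–128 selection coefficients per group with no distributional
assumption. Paired t, Welch t and one-way ANOVA with Šídák-corrected pairwise
comparisons ($p_{adj} = 1-(1-p)^m$) are selectable where a specific
experimental design calls for them. Raw and adjusted p values are reported.

# Flow cytometry

**GFP gating.** The threshold is the 99.9th percentile of a non-fluorescent
control run alongside the sample — an explicit, monotone-transform-invariant
replacement for the manual gates typically drawn in flow-cytometry software. By construction ~0.1% of control-like events
fall above the gate.

**DNA content.** The 1C and 2C peaks are the two most prominent local
maxima of a Gaussian kernel density (Silverman bandwidth, 512-point grid);
the smaller position is 1C. Percent cell-cycle progression is the printed
formula $((H - 1C)/(2C - 1C)) \times 100$ with $H$ the histogram mean;
values outside [0, 100] are reported as-is. The S-phase gate places
windows of half-width $w \cdot (2C-1C)/2$ (default $w = 0.2$) around both
peaks and counts events strictly between them. This interval gate is a
slightly biased estimator of a latent S-phase fraction: the windows
truncate the ends of the replication bridge (≈ $-w$ of the S fraction)
while Gaussian peak tails spill into the interval (≈ +1.9 percentage
points at CV 5%); at the default settings the net expectation for a
planted 16% bridge is ≈ 14.7–16.5%, and the acceptance check allows ±2
percentage points accordingly. The explicit interval rule was chosen, and
its bias documented, in preference to hiding the gate inside a fitted
mixture model.

**Growth.** Cumulative generations over serial-dilution cycles are
$\sum \log_2(\mathrm{OD_{end}}/\mathrm{OD_{start}})$, additive over cycles,
negative for declining cultures.

# Localization ratio and pulses

Per cell, the localization ratio is

$$\frac{(q_{95} - \mathrm{median}) - (\mathrm{median} - q_{05})}{q_{75} - q_{25}}$$

over the cell's GFP pixel intensities — a tail-asymmetry variant of
Bowley's quantile skewness. It is exactly zero for symmetric pixel
distributions, exactly invariant under positive affine intensity
transforms (illumination and offset changes), and positive when a bright
nuclear sub-population creates a long upper tail. Cells with fewer than 20
pixels are excluded (extreme quantiles of tiny samples are unstable), as
are cells with zero interquartile range.

The nuclear-scoring threshold θ = 0.5 replaces manual visual scoring; it
sits near mean + 3 sd of the ratio distribution of generator cells without
any nuclear sub-population (checked in the test suite), and well below the
ratios produced by a 10%-of-pixels nuclear component at 3-fold enrichment
(≈ 1 and above). A pulse is a maximal run of frames with ratio > θ;
duration is run length × frame interval (one 30-s frame = 0.5 min), and
pulses of ≤ 5 min are classified brief. Cells are independent; no
gap interpolation is attempted — a tracking gap would terminate a pulse.

# Synthetic data: what it emulates, and what it does not

All generators are seeded and bit-reproducible, and they restore the
session RNG state. Defaults mirror the study geometry: 256 genotypes + WT,
depth 1e5 reads/timepoint, {0, 24, 48, 72} h, 4 replicates; 5000 events
per flow sample; 30-min traces at 0.5-min spacing; DNA histograms with
peaks at 100/200 (CV 5% — typical of a well-stained yeast Sytox
histogram) and an asynchronous 60/16/24 G1/S/G2 composition.

The pooled-screen generator uses deterministic exponential drift
($f_v(t) \propto f_v(0)\,2^{s_v t}$, renormalized) with multinomial
sampling noise at sequencing depth. It does not model dilution
bottlenecks (an explicit bottleneck can be layered on by resampling
counts against an assumed census size), PCR
amplification bias, or index hopping — so recovery tests validate the
estimator under sampling noise, not library-prep artifacts. The read
generator plants expected sequences at random offsets with iid
substitution errors; it does not emulate quality-score structure, which
the counter deliberately ignores. The pixel generator uses symmetric
Gaussian backgrounds; real cytoplasms are weakly right-skewed, which
shifts the no-nucleus ratio distribution slightly positive — one reason θ
is set conservatively at 0.5. Passing recovery tests therefore
demonstrates estimator correctness under the stated noise models, not
robustness to every artifact of real screens.

# Problem sizes and numerical choices

The test suite and the acceptance script run the screen-recovery check at
full study scale (257 variants × 4 timepoints × 4 replicates at depth
1e5), and exercise the remaining estimators at reduced scale (32-genotype
libraries, 2–3 replicates, depth 1e4–2e4) where the property under test
does not require full depth; the reduced sizes keep the whole suite under
half a minute while leaving the noise regimes representative. Degenerate
inputs fail loudly rather than silently: all-zero count columns, fewer
than two timepoints, non-increasing times, zero IQR, single-peak DNA
histograms, overlapping S-phase windows, and contradictory subset
constraints are all errors with specific messages. OLS fits use
`stats::lm`; ties in the heatmap order and quantile conventions are fixed
as described so every pipeline output is a deterministic function of
(inputs, seed) — reruns are byte-identical, which the tests assert.

# Known limitations

- Selection coefficients are log-linear slopes; saturation between
  dilutions (cultures approaching stationary phase) bends the trajectories
  and is absorbed into the slope rather than modeled.
- The per-hour unit is a convention; reporting per day or per timepoint is
  a fixed multiplicative rescaling, and comparisons across studies must
  check which unit is in use.
- The pairwise statistic assumes a two-strain closed system; cross-feeding
  or flocculation would violate the shared-denominator argument behind the
  log2-odds form.
- The S-phase interval gate and the KDE peak finder are intentionally
  simple; histograms with strong aneuploidy or heavy doublet contamination
  need curation upstream.
- Exact-match counting discards every read with any error inside the
  windows; at error rate $e$ and combined window length $L$ the assigned
  fraction is $(1-e)^L$, a depth cost, not a bias — misassignment requires
  a specific multi-base error pattern and is not observed in exhaustive
  single-substitution tests.
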