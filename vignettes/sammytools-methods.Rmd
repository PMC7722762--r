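---
title: "Models and methods behind sammytools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sammytools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sammytools)
```

## The assay and the analysis problem

Sequential chromatin fractionation sequencing (SAMMY-seq) separates
chromatin into pools of decreasing solubility/accessibility — a
DNase-released fraction (S2), a high-salt-released fraction (S3), and a
urea-solubilized, most condensed fraction (S4) — and sequences each pool.
Megabase-scale heterochromatic regions (notably lamina-associated domains,
LADs) are enriched in the less accessible fractions and depleted in the
more accessible ones. The analysis task is to turn per-fraction aligned
fragment coordinates into:

1. binned, library-normalized coverage and smoothed differential signal;
2. broad *enrichment domains* from a pair of fractions (the less accessible
   fraction against the more accessible one used as a baseline);
3. statistics of agreement between interval sets (domain calls, LADs,
   histone-mark domains): Jaccard indices, precision/sensitivity,
   shuffle-randomization and Fisher tests, consensus/conservation;
4. signal metaprofiles around domain borders and TSSs;
5. genome-wide kernel correlations between tracks;
6. chromatin-state-stratified aggregation of transcript-level
   differential-expression p-values; and
7. quantification of nuclear-foci proximity to the nuclear periphery in
   fluorescence images.

Every stage is exercised end-to-end on a synthetic-data generator that
reproduces the statistical structure the analysis assumes, so the package
is fully testable without sequencing data.

## The synthetic-data generator

The generator is first-class, tested code; its defaults define the
conditions all property tests and the acceptance script run under.

**Domain architecture.** `make_architecture()` places `n_domains`
(default 10) non-overlapping domains with lengths uniform in
`size_range` (default 1–5 Mb) uniformly at random on a toy genome
(default 2 chromosomes × 30 Mb, at least ten times the largest domain).
Placement is rejection sampling with bounded retries; an impossible
packing fails with an explicit message.

**Fraction reads.** `simulate_fraction_reads()` draws read midpoints from
a genome-wide multinomial whose per-bp weight is the enrichment factor
*f* (default 3) inside the planted domains for S4, `1/f` for S2, and an
intermediate factor for S3, with weight 1 elsewhere. No published
generative model exists for the assay; this is the minimal structure under
which enrichment of a less accessible fraction over the S2 baseline is
well defined. The S3 level relative to S4 is not characterized in the
literature, so it is a free parameter defaulting to `sqrt(f)`. Note the
in-domain S4/S2 density ratio is `f^2` by construction. The "disrupted"
condition (progeria-like profiles) re-draws each read with probability
`disruption_rho` (default 0.5) from a uniformly random re-placement of the
domains, flattening and scattering the contrast without asserting any
mechanism.

**Reference tracks, states, transcripts, nuclei.**
`simulate_mark_track()` produces ±1 indicator tracks of the domains plus
Gaussian noise (polarity +1 emulates Lamin/H3K9me3-like tracks, −1
open-chromatin tracks). `paint_chromatin_states()` partitions the genome
into 10 Roadmap-style mnemonics with exponential segment lengths
(mean 50 kb): domains are mostly Het/Quies (70% expected) with minority
Polycomb/bivalent islands; outside is mostly Tx/TxWk/Quies.
`simulate_transcript_table()` places transcripts uniformly; transcripts
whose 200-nt TSS window is bivalent draw `p ~ Beta(effect, 1)` with a
positive signed effect with probability 0.8; all others are exactly null.
`simulate_nuclei()` renders one elliptical nucleus per image (axis ratio
0.85–1) with bright 2-D Gaussian foci whose radial position is pulled
toward the periphery with strength `periphery_bias`; at bias 1 the radial
draw is clamped to the outer shell (true proximity ≤ 0.2). Foci centers
are kept at least five focus widths apart so the ground truth and the
detections correspond one-to-one. Ground-truth boundary distances and
proximities are computed from the continuous ellipse, not from pixels.

What the generator deliberately does **not** model: sequence content and
read errors (no FASTQ), GC or mappability bias, diploidy,
replicate-correlation structure beyond independent seeds, 3-D image
stacks. Passing tests therefore demonstrate correctness of the
*algorithms* under the stated statistical structure, not robustness to
artifacts absent from the model.

## Domain calling

`call_domains()` composes: binning (default 10 kb on the toy genome; the
deep-data parameterizations ship as presets — SAMMY gap 25/bin 50 bp,
H3K9me3 fdr 0.1/gap 10/bin 100, Lamin A/C gap 25/bin 200, Lamin B1 gap
5/bin 100); a library-normalized log2 ratio with pseudocount
`c = 0.5` reads per bin,

$$\mathrm{value}_i = \log_2 \frac{(t_i + c)/T_\mathrm{eff}}
{(r_i + c)/R_\mathrm{eff}}, \qquad
T_\mathrm{eff} = \textstyle\sum_i t_i + c\,n_\mathrm{bins},$$

so a global scale difference cancels exactly and every bin is finite; bin
scoring; maximal-segment extraction; and a permutation null.

**Bin scoring.** Informative bins (outside the blacklist, non-zero
reference coverage) score +1 when their log-ratio exceeds a data-driven
split point and −G (the *gap penalty*) otherwise; non-informative bins
score 0. Ties at the split point are non-enriched (strict `>`), so
constant input yields no enriched bins. The default split point maximizes
the between-class variance of the informative log-ratios (Otsu's
criterion applied to the raw values). A strict median split is available
(`threshold_method = "median"`), and the two coincide whenever the
enriched mode covers less than half of the informative genome and the
modes are separated. We made the variance-based split the default because
the median is a biased estimate of the mode boundary when enriched
regions approach or exceed half the genome — exactly the regime of the
default architecture (10 domains of 1–5 Mb on 60 Mb cover half the genome
in expectation). Empirically, at a planted coverage of 53% the median
split drops domain recovery to JI ≈ 0.63 while the variance split stays
at ≈ 0.998; below 50% coverage both give ≈ 0.998.

**Maximal segments.** All maximal scoring subsequences are extracted with
the linear-scan Ruzzo–Tompa algorithm: every reported segment has positive
total score, segments are disjoint, and no extension or trimming increases
a segment's score. The implementation is verified against an exhaustive
quadratic oracle (recursive extraction of the maximum-sum subarray,
shortest-then-leftmost tie break) on random score vectors.

**Significance.** The exact Monte-Carlo scheme of the original
broad-domain caller is not published; we use a genome-wide score-label
permutation against the *maximum* segment score (a conservative,
family-wise-flavored null): for each of `n_permutations` (default 1000)
shuffles of the informative-bin scores, the maximum segment score across
the genome is recorded, and segment
`p = (1 + \#\{\mathrm{perm max} \ge \mathrm{observed}\})/(1 + N)`,
followed by Benjamini–Hochberg correction across segments. Calls need
`q ≤ fdr` (default 0.05; 0.1 in the H3K9me3 preset) *and* an
informative-bin fraction ≥ 0.98. Fewer than ~1000 permutations limits the
attainable q-values when many segments compete (p-values are bounded
below by `1/(N+1)`), which matters for weak, scattered signal; the
default keeps the p-resolution comfortably below the fdr cutoff.
Equivalence with the original caller's numbers is *not* claimed — the
package's claims are recovery of planted truth and internal calibration,
both tested.

`broad_peaks()` provides the single-track analogue for histone marks:
fixed windows (default 2000 bp), a z-score against a genome-wide Poisson
mean, threshold z ≥ 3, adjacent significant windows merged.

## Overlap statistics

All interval algebra is exact at base-pair resolution (0-based, half-open
throughout, including bin grids; bin *i* covers `[i·b, (i+1)·b)` and the
final partial bin is kept). `empirical_overlap_test()` re-places every
interval of one set uniformly at random (lengths and count preserved,
blacklist excluded, mutual overlap forbidden by default, chromosome
re-assignment allowed by default with a `preserve_chrom` option — the
randomization reference tool's default does not preserve chromosomes) and
uses the `(k+1)/(N+1)` one-tailed estimator, which is never zero: with
10,000 randomizations and no random JI reaching the observed one, the
smallest reportable p is 1/10001. `fisher_overlap_test()` builds the 2×2
bin-occupancy table explicitly (default 10-kb bins; the table is returned
for audit, because contingency constructions differ subtly between tools)
and takes the hypergeometric upper tail. `multi_sample_overlap()` returns
bases covered by ≥ `min_support` samples (consensus) and each sample's
fraction covered by *all* samples (conservation).

## Metaprofiles

`border_profile()` samples a track in ±`k_bins` (default 50) bins around
each domain border, oriented so the domain interior is on the positive
side of a start border and the negative side of an end border (the
orientation is fixed and tested: a symmetric signal gives mirrored
start/end profiles). Out-of-bounds positions are missing, not zero. The
displayed smoother is a cubic smoothing spline with GCV-selected penalty;
the quantity of record is the unsmoothed per-position mean ± SEM, so the
smoother choice is cosmetic. `tss_profile()` uses strand-oriented windows
(±5000 bp in 100-bp bins by default, i.e. 101 positions).
`common_peak_gene_set()` intersects peak sets across all samples and
selects genes whose half-open `[TSS−500, TSS+500)` window touches a
common region by ≥ 1 bp.

## Kernel correlation

`kernel_correlation()` smooths both tracks per chromosome with a Gaussian
kernel (SD in bins, default 3, reflective boundaries) and reports the
genome-wide Pearson correlation of the smoothed tracks; SD 0 is plain
Pearson. This defined estimator preserves the meaning of a kernel
correlation — tolerance to spatially related but imperfectly overlapping
features — and is invariant under positive affine transforms of either
track; it is *not* numerically equivalent to any particular external
tool. `kc_null()` builds a null by circular per-chromosome shifts
(preserving each chromosome's value multiset) and reports a z-score and
the `(k+1)/(N+1)` empirical p.

## Expression aggregation

Transcripts are assigned chromatin contexts by two rules: body states
(Tx, TxWk, ReprPC, ReprPCWk, Het, ZNF/Rpts) require ≥ 50% of the body
overlapped by the state; bivalent states (TssBiv, BivFlnk, EnhBiv) require
the 200-nt window centered on the TSS (TSS ± 100 nt) to overlap the state
by ≥ 100 nt. Group p-values use Lancaster's method,

$$T = \sum_i Q_\Gamma\!\left(\tfrac{w_i}{2},\, 2;\, 1 - p_i\right)
\sim \chi^2_{\sum_i w_i} \text{ under the null},$$

with all weights 2 by default, which is exactly Fisher's method (verified
to 1e-10 against the closed form); a supplied-weights mode accepts
abundance-style weights, since the weights used in published runs of this
aggregation are generally not reported. p-values of 0 are clamped to
1e-300 (the gamma quantile diverges at 1). Up- and downregulated
transcripts (sign of the effect) aggregate separately by default; BH runs
across all rows of a run; `rank_groups_across()` ranks groups by the sum
of −log10 p over conditions. `bivalent_enrichment_test()` is a one-tailed
hypergeometric test of bivalent-gene enrichment among hits.

## Foci image analysis

Nuclei: global two-class Otsu threshold, 8-connectivity components, hole
filling, removal of components under 200 px or touching the border —
each a fixed, logged parameter. Foci: within each nucleus independently,
an exhaustive two-threshold Otsu search on a 256-bin histogram of that
nucleus's intensities (deterministic); the top class forms candidate
foci; components under 2 px are dropped; sub-resolution merged spots
count once. Proximity: the minimum Euclidean distance from any focus
pixel to a background pixel of its nucleus, divided by the distance from
the nucleus centroid to that boundary pixel, clamped to [0, 1] — a
size-independent measure that is 0 at the periphery and 1 at the
centroid. Ties for the nearest boundary pixel break in raster order,
which moves the boundary point by at most one pixel of geometry. On
analytic circles the measured distances match `r_nucleus − r_focus`
within a pixel, and proximity is stable (< 5% change) under 2×
resampling.

## Numerical choices and degenerate inputs

- Gaussian differential signal: kernel SD default 150 bp, step 50 bp
  (both configurable; the upstream smoother's default bandwidth is not
  printed in the methods it emulates), tag shift 0. The kernel is
  truncated at ±6 SD: the truncated evaluation matches an untruncated
  dense sum to < 1e-6 of the peak height, which a 4-SD cut does not
  achieve.
- Pseudocount 0.5 reads per bin in the log ratio, recorded in the track
  metadata.
- Down-sampling operates on aligned coordinates as independent Bernoulli
  thinning — equivalent in distribution to sampling raw reads for
  everything downstream of alignment.
- Empty interval sets: `jaccard` of two empty sets warns and returns 0;
  an empty query in `coverage_fraction` is an error.
- Constant images are rejected; nuclei under 10 px are skipped with a
  warning; a focus pixel outside its nucleus mask is a hard error.
- Border windows that overlap a neighboring domain are included in
  metaprofiles (whether published metaprofiles excluded them is
  unstated); all windows enter the mean.
- Every generator and every Monte-Carlo routine takes an explicit seed
  and restores the caller's RNG state.

## Problem sizes used by the tests

The test suite and the acceptance script run at desk scale, chosen so the
whole suite completes in minutes on one CPU while every statistical check
retains power: 2 × 30 Mb genomes, 1 M reads per fraction for calling
(down to 1–3 × 10^5 for replicate contrasts), 1000 caller permutations,
200-replicate calibration of the shuffle test at N = 199, 20 + 50
replicates for aggregation recovery/null, and 50 synthetic nuclei per
condition for the imaging checks.

## Known limitations

- The caller has no replicate-aware joint model and no local
  (per-chromosome) background; the gap penalty is never auto-estimated.
- The shuffle and Fisher overlap tests assume intervals are exchangeable
  across the non-blacklisted genome; no isochore- or composition-matched
  randomization is provided.
- Kernel correlation reports a single genome-wide number, not a
  correlation-versus-distance profile.
- The transcript aggregation consumes an upstream differential-expression
  table as-is; it does not model the upstream test's dependence structure.
- Image analysis is strictly 2-D, single-channel, one nucleus per
  connected component.

## A minimal worked run

```{r example, eval = FALSE}
arch <- make_architecture(c(chrA = 30e6, chrB = 30e6), n_domains = 10,
                          size_range = c(1e6, 5e6), enrichment_factor = 3,
                          seed = 7)
s4 <- simulate_fraction_reads(arch, "S4", 1e6, seed = 1)
s2 <- simulate_fraction_reads(arch, "S2", 1e6, seed = 2)
calls <- call_domains(s4, s2, arch$genome, bin_size = 1e4,
                      gap_penalty = 25, n_permutations = 1000, seed = 3)
summary(calls)
jaccard(as_intervals_calls(calls), arch$closed_domains)
```

See the README for the numbers this prints and
`scripts/acceptance.R` for the full set of recomputed quantities.
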