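---
title: "Calling time-resolved copy-number alterations with cnadapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling time-resolved copy-number alterations with cnadapt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnadapt)
library(dplyr)
```

## The problem

When proliferating cell populations are placed under a sustained
selective pressure that also elevates chromosome missegregation — for
example long-term inhibition of the spindle assembly checkpoint kinase
MPS1 — their karyotypes evolve. Populations acquire whole-chromosome,
arm-level, and focal copy-number alterations (CNAs), and over weeks of
culture the fittest alterations sweep while early, less beneficial ones
are lost. Low-coverage whole-genome sequencing of many independently
adapting populations at successive time points turns this process into
data: per-sample read counts in fixed genomic bins, from which
population-average copy number can be estimated and compared with the
untreated parental line.

cnadapt implements the full analysis path from binned counts to cohort
statistics:

1. GC-bias correction and normalization to copies
   (`correct_gc()`, `normalize_to_copy_number()`);
2. exact change-point detection per chromosome with PELT (`pelt()`,
   `segment_profile()`);
3. differential state calling against the matched parental profile
   (`harmonize_breakpoints()`, `call_states()`, `propagate_flags()`,
   `merge_same_state()`), wrapped by `call_cna()`;
4. event classification into whole-chromosome / arm / focal
   (`classify_events()`);
5. cohort aggregation and association statistics
   (`aneuploidy_burden()`, `frequency_table()`,
   `cna_type_proportions()`, `association_ftest()`,
   `anticorrelation_scan()`, `cancer_frequency_correlation()`);
6. a synthetic-data generator with known ground truth
   (`simulate_karyotype()`, `simulate_profile()`, `simulate_cohort()`)
   that every stage is validated against.

## Coordinate frame

All coordinates are 0-based half-open (BED convention). A
`genome_layout` lists chromosome lengths, centromere intervals,
acrocentric flags, and per-chromosome baseline copy numbers; the bin
grid (default 500 kb) is derived from it. Bins overlapping the
centromere interval are masked, as are all p-arm bins of acrocentric
chromosomes — only acrocentric q arms carry signal in this kind of
data. Arm membership of a bin is decided by its midpoint relative to
the centromere midpoint, which is deterministic for bins straddling
the boundary. Masked bins are excluded from segmentation and from
burden denominators. Bin-count-based spans treat every bin as
`bin_size` wide; the final bin of a chromosome may be shorter, a
negligible approximation at 500 kb.

A four-chromosome `toy_genome()` (164 usable bins, one acrocentric
chromosome) supports desk-scale simulation and testing;
`human_genome()` loads a bundled GRCh38-like layout (approximate
lengths and centromeres, acrocentric 13/14/15/21/22) for
realistic-scale runs.

## Preprocessing: from counts to copies

Bin counts from low-coverage WGS carry a smooth dependence on local GC
content. `correct_gc()` models the expected count as a function of GC
with a natural-spline quasi-Poisson regression (log link, `df = 4`)
and divides each count by the fitted factor. Two details matter:

* **Copy-number awareness.** In a single sample, copy number and GC are
  confounded: if an altered arm happens to occupy one end of the GC
  range, a naive fit absorbs part of the alteration into the "bias"
  curve and shrinks the very signal we want to call. The correction
  therefore scores every arm against the genome's dominant arm level
  (the median of per-arm median ratios — arms are equal-weighted, so
  one large aneuploid chromosome cannot drag the reference) and refits
  the curve using only bins of arms within 10% of that level. If too
  few bins remain the fit falls back to all usable bins.
* **Global regression, not a scatterplot smoother.** Local smoothers
  (LOWESS-type) give the sparse GC extremes high leverage; bins out
  there are exactly the ones that end up systematically mis-corrected.
  A low-degree-of-freedom global fit borrows strength across the whole
  GC range.

`normalize_to_copy_number()` scales corrected counts to copies
(2 = disomic at a diploid baseline). The anchor is the median corrected
count over *euploid arms* — arms within 10% of the dominant
(baseline-adjusted) arm level. A plain genome-wide median is offered as
`anchor = "median"`, but it drifts in proportion to the altered
fraction of the genome (a ~4% inflation with 14% of bins gained) and
breaks outright when more than half of the genome is altered; the test
suite documents that breakdown. Because downstream state calling is
differential (sample minus parental), any anchor error shared by the
two profiles cancels.

Sex-chromosome baselines are configuration, not code: set
`baseline_cn` per chromosome in the layout, and flag known
karyotype-by-history regions (for example an X disomy in a
diploidized male line) through the flag mechanism described below.

## Segmentation

Change points are detected per chromosome with PELT, the pruned exact
linear time algorithm. The cost is Gaussian change-in-mean,
`C(seg) = sum((x - mean(seg))^2) / sigma2`, minimized over all
segmentations with segments of at least `min_seg = 2` points plus a
penalty `beta` per change point. PELT prunes candidate split points but
returns the exact global optimum; the package ships an O(n^2)
optimal-partitioning oracle (`optimal_partitioning()`) and the test
suite proves equality on hundreds of random instances. Two
implementation notes:

* With a minimum segment length above 1, classic PELT pruning is
  slightly too eager: a candidate dominated at time `t` is only
  provably dominated once the competing path's last segment is
  admissible. Pruning is therefore delayed by `min_seg` positions.
* Ties between optima are broken toward fewer change points, then the
  earliest boundaries, so results are deterministic.

Detection runs on the square root of the copy-number track: count
noise grows with copy number, and the square-root transform
approximately stabilizes the variance so that a single noise estimate
fits altered and unaltered chromosomes alike. Segment means are
always reported on the copies scale. The noise variance `sigma2` is
estimated per sample from lag-1 differences pooled across chromosomes,
as `(MAD / sqrt 2)^2` — differences are insensitive to the sparse true
change points, and pooling genome-wide removes the instability of
per-chromosome estimates on 20–60 bins.

The bare `pelt()` default penalty is the BIC-like `2 log n`. The
pipeline (`segment_profile()` and everything above it) defaults to
`3 log n`: per-chromosome series are short, `sigma2` is estimated
rather than known (which measurably inflates the false-positive rate
of the factor-2 penalty), and the downstream one-to-one alignment and
strict structural event definitions are sensitive to over-segmentation.
The penalty was calibrated so that spurious fragments are rare on
simulated flat profiles; it remains an exposed knob.

By convention, a chromosome in which at least one change point is
found anywhere is additionally split at the centromere, so arm-level
and focal changes can be distinguished; a chromosome with no change
points stays one segment spanning both arms. The split is applied by
re-running detection on each arm separately under the forced boundary.
Re-segmenting, rather than inserting the extra cut into the
genome-wide solution, matters in practice: when the detected boundary
sits a bin or two off the true arm boundary, naive insertion leaves a
stray one-bin fragment beside the centromere whose state then vetoes a
clean arm call; within a single arm that fragment no longer pays for
its penalty and disappears.

## Differential state calling

Copy number is interpreted relative to the matched untreated parental
(wild-type) profile. Sample and parental segmentations are re-cut on
the union of their change points (`harmonize_breakpoints()`), giving a
one-to-one correspondence with per-segment means recomputed on each
profile's own copy numbers. Each aligned segment gets
`delta = mean_cn_sample - mean_cn_ref` and a state: gain (G) when
`delta > +0.5`, loss (L) when `delta < -0.5`, equal (E) otherwise.
The inequalities are strict — a delta of exactly +0.5 is E. On the
population-average scale this threshold has a simple meaning: a
single-copy alteration must be present in the (clonal) majority of the
population to cross 0.5.

Changed segments shorter than 15 bins (7.5 Mb at 500-kb bins) are not
counted: they are relabeled E and recorded in a filter log rather than
dropped, so the genome partition stays intact and the relabeling is
auditable. The alignment step over-segments by construction (it copies
each profile's change points onto the other, and the centromere
heuristic adds more), so adjacent segments with the same state are
merged back (bin-weighted means); merging crosses the centromere
exactly when both flanking segments agree, restoring the
single-segment representation of an unchanged or fully changed
chromosome. Order matters here: merging runs on the *pre-filter*
states, and the minimum-length rule is then applied to the merged
segments (both stages are logged). Applying the length filter strictly
before merging would let one copied wild-type breakpoint split a full
arm into two sub-15-bin pieces that could never be counted again.

Regions with pre-existing parental CNAs are supplied as a flag table;
any segment overlapping a flagged region by at least one bin is set to
the ignore state `i`, which overrides G/L/E and excludes the segment
from all downstream accounting (numerators and denominators alike).

## Event classification

The merged, state-labeled partition is classified per chromosome:

* **whole-chromosome** — every non-ignored usable bin shares one
  changed direction (both arms observable);
* **arm** — one full arm changed, the chromosome not;
* **focal** — each maximal changed run covering a strict subset of an
  arm.

The definitions are structural (no fractional-coverage tolerance). A
changed run spanning all of one arm plus part of the other decomposes
into an arm event and a focal event. Acrocentric chromosomes are
represented only by their q arm; a fully changed q arm is reported as
an arm event by default, or as a whole-chromosome event under
`acrocentric_as_whole = TRUE`, and cohort summaries can be produced
under either convention.

## Cohort statistics

* `aneuploidy_burden()` — fraction of the usable, non-ignored genome
  covered by qualifying events. Aneuploidy means whole-chromosome and
  arm events; focal events are included only on request.
* `frequency_table()` — per cell line, day, arm, and direction: the
  percentage of populations with at least one qualifying event.
  Whole-chromosome events count toward both arms.
* `cna_type_proportions()` — shares of whole/arm/focal among all
  classified events per day; the counting unit is one event per
  maximal changed run.
* `association_ftest()` — ordinary least squares `y = a + bx` with the
  overall F-test on (1, n-2) degrees of freedom; with a 0/1 indicator
  as x this is the standard two-group comparison of growth between
  populations with and without an aneuploidy. p-values are reported
  raw, matching how such panels are usually annotated; a
  Benjamini-Hochberg column can be added by the caller via
  `p.adjust()`.
* `anticorrelation_scan()` — pairwise indicator associations plus 2x2
  co-occurrence tables, for detecting mutually exclusive aneuploidies.
* `cancer_frequency_correlation()` — Pearson r and regression F-test
  between the cohort's mean per-arm frequencies (unweighted mean over
  cell lines) and an external per-arm frequency table read from CSV.
  The package ships only a synthetic example table
  (`synthetic_cancer_arm_frequencies.csv`); real tumor-atlas tables
  are inputs, not package data.

## The synthetic-data generator

`simulate_cohort()` produces everything the pipeline consumes with
known ground truth. Design choices:

* **Counts** are negative binomial around
  `mean_reads * (cn / mean cn) * bias(gc) / mean bias`, with
  dispersion (size) 100 by default — a mild overdispersion (variance
  1.5x the mean at 50 reads) typical of low-coverage WGS bins; the
  Poisson limit is reached as the size parameter grows.
* **GC** is a genome property: one draw per layout (beta-shaped on
  0.3–0.6), shared by all samples, so a correction method can cancel
  the bias in principle. The default bias curve is quadratic with a
  ~1.5-fold max/min range.
* **Karyotypes** compose additively from whole/arm/interval events;
  subclone mixtures yield non-integer population-average copies
  (`fractions` weights), which is exactly what low-coverage sequencing
  of a mixed population measures.
* **Cohorts**: regions carry per-day population frequencies; presence
  is sampled independently per population (a `deterministic` mode
  assigns `round(freq * n)` populations exactly). Rows sharing a
  `group` are mutually exclusive within a population-day, which models
  a whole-chromosome event replaced over time by its arm-level
  refinement. Trajectories are inputs; the generator deliberately
  implements no explicit selection dynamics.
* **Growth**: `growth_plus_rev = baseline + sum(beta * indicator) +`
  Gaussian noise, normalized to the untreated parental line; the
  default baseline of 0.04 and 90-day planted frequencies reproduce an
  adaptation-like time course in which whole-chromosome changes
  dominate early (>60% of events at day 30) and arm plus focal changes
  roughly double their share by day 90.

What the generator does *not* emulate: mappability and
replication-timing structure, segmental duplications, GC curves that
differ between libraries, read-level artifacts, whole-genome doubling,
and clonal interference within a population (each region's subclone
fraction is fixed, not evolving). Passing tests therefore demonstrate
correctness of the algorithms under a realistic noise model, not
robustness to every artifact of real sequencing.

## Validation and problem sizes

The test suite validates each stage against independent oracles:
exhaustive enumeration and O(n^2) dynamic programming for PELT;
interval arithmetic for masking; closed-form OLS for the F-test;
planted ground truth for end-to-end recovery. The default validation
sizes are a 164-bin toy genome, 20-population cohorts at 50 reads per
bin, 500 random segmentation instances at n <= 60, and 10,000
F-test null replicates at n = 20 — all chosen so the whole suite runs
in about two minutes on one core. Under those conditions planted
clonal arm events are recovered end-to-end with >=95% sensitivity and
<5% false arm-level calls, and subclonal events at population fraction
0.2 stay below the calling threshold, consistent with the
clonal-majority semantics of the +-0.5 rule.

Two implementation defects were caught by the oracle tests during
development and are worth recording: the cost reported by the
segmentation originally double-counted one penalty term, and classic
PELT pruning had to be delayed by `min_seg` positions to stay exact
under a minimum segment length. Both are now covered by invariant
tests.

## Worked example

```{r example, eval = FALSE}
layout <- toy_genome()
set.seed(1)
gc <- simulate_gc(layout)

parental <- simulate_profile(layout, simulate_karyotype(layout),
                             gc = gc, sample_id = "parental")
kar <- simulate_karyotype(layout, tibble::tibble(
  chrom = "chrT2", region = "q", delta = 1L))
adapted <- simulate_profile(layout, kar, gc = gc, sample_id = "d90")

calls <- call_cna(preprocess_profile(adapted, layout),
                  preprocess_profile(parental, layout), layout)
calls$events
glance(calls)
aneuploidy_burden(calls)
plot_cn_profile(preprocess_profile(adapted, layout), layout, calls)
```

## Known limitations

* Population-average semantics only: no subclone deconvolution; a
  fraction-0.2 event is by design reported as "no change".
* The structural arm/whole definitions are knife-edged by
  construction; a single mis-corrected boundary bin can demote a
  whole-chromosome event to an arm or focal event. The conservative
  penalty and per-arm re-segmentation make this rare at 50 reads/bin,
  not impossible.
* The euploid-arm anchor assumes most *arms* are at baseline; a
  genome where the majority of arms are altered will be normalized
  against a wrong reference level (the plain median anchor fails
  earlier, at half the *bins*).
* `cancer_frequency_correlation()` requires at least 10 shared arms
  and therefore needs a realistic layout, not the 7-arm toy genome.
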