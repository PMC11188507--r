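---
title: "Building consensus CNV benchmarks from replicated caller cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building consensus CNV benchmarks from replicated caller cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvconsensus)
```

## The problem

Somatic copy-number variation (CNV) callers disagree — across replicates of
the same library, across sequencing centers, and above all across
algorithms. On a hyper-diploid cancer genome (overall ploidy well above 2,
as in the HCC1395 breast-cancer cell line with ploidy near 2.85) the
disagreement is dominated by how each caller anchors the copy-neutral
level: a caller that centers on the genome median coverage will call
genome-wide gains or losses when the median does not correspond to two
copies. `cnvconsensus` implements a reproducibility-weighted consensus over
many caller-by-replicate call sets, validates the consensus against
orthogonal (non-NGS) technologies, and assembles a high-confidence
gain/loss/LOH benchmark, together with the region-based metrics used to
evaluate callers against it.

Everything is length-based. Coordinates are 0-based half-open (BED
convention); all reported lengths are `end - start` sums, printed in Mb as
length / 10^6. Calls are typed from total copy number: gain above 2, loss
below 2, and at exactly 2 either copy-neutral LOH (minor allele absent) or
neutral. Copy numbers may be fractional, so equality with 2 uses a 10^-6
tolerance; the published cutoffs are stated on integers and the tolerance
only disambiguates floating-point caller output.

## Consensus scoring

The unit of scoring is the disjoint interval: all typed regions of all
call sets are partitioned so that every output interval is covered either
fully or not at all by each call set (the classical `multiinter`
operation, implemented here on `GRanges`). A call supports an interval if
its typed region covers it; because the partition is exact, partial
overlaps cannot occur at this granularity.

Replicate support is aggregated in two stages:

1. **Within and across centers.** The 21 replicates of the default layout
   are divided into five groups per caller: three triplicate centers
   (groups 1–3), one nine-replicate center whose supporting count is
   divided by 3 so it cannot dominate (group 4), and the pooled
   single-replicate centers (group 5). Each group contributes 0–3; the
   cumulative score per caller lies in [0, 15] and converts to a 0–3
   scale: 10–15 → 3, 7–9 → 2, 4–6 → 1, 0–3 → 0. The cumulative score is
   linear in replicate support (each supporting replicate adds
   1 / divisor), which is how `score_cohort()` vectorizes it.
2. **Across callers.** The converted scores are summed over the six
   callers (0–18 for gain and loss) and mapped to confidence levels:
   11–18 strong, 8–10 medium, 4–7 weak, 1–3 neutral. LOH is reported by
   five callers only (one caller reports no LOH and is dropped from the
   LOH scale with a warning), and uses its own scale: strong strictly
   above 8, 6–7 medium, 4–5 weak, below 3 neutral.

Two boundary choices were genuinely open and are resolved as follows:

* The LOH scale leaves totals of exactly 8 and exactly 3 unassigned. Both
  gaps close downward (8 → medium, 3 → neutral), preserving the only
  strict inequality in the stated scale ("greater than 8" for strong).
* A total score of 0 maps to `NONE` rather than neutral. It cannot arise
  from partitioning (every interval has at least one supporting call
  set, and one supporting replicate gives a cumulative score of 1), but
  the label keeps degenerate masked inputs distinguishable — and with
  small grouping schemes a supported interval can still convert to 0.
* Fractional cumulative scores (the nine-replicate group contributes
  thirds) are binned by reading the integer ranges as the intervals
  [0,3], (3,6], (6,9], (9,15]; this is the minimal extension consistent
  with the integer labels and is unit-tested at the edges.

An exclusion mask is applied before scoring. For the study genome this
removes the p-arm of chr6, the q-arm of chr16, chrX (regions wholly lost
in the cell line), and assembly gaps; since no gap-track version is
canonical, the mask is an input, with a synthetic example fixture in
`inst/extdata/exclusion_mask_synthetic.bed`.

## Orthogonal validation and benchmark assembly

Validation is per-base: a consensus interval is validated by a technology
over exactly the bases where the technology calls the same type, so an
interval can be partially validated and all summary rows are denominated
in Mb (`validation_table()` reports, per confidence level, the collapsed
length, each technology's validated length, and the lengths validated by
at least one and at least two technologies). Replicate calls of one
technology are first collapsed with `cluster_nonredundant()`:
single-linkage over same-type calls whose positions lie within 10 kb and
whose sizes agree better than 50%, each cluster replaced by the
median-coordinate, median-copy-number representative. The proximity test
is applied to the call position (start): requiring both breakpoints to
agree within 10 kb would make the size-similarity criterion unsatisfiable
for calls of visibly different size, which the rule is explicitly meant
to admit.

The benchmark keeps strong-evidence intervals unconditionally (their
validation rate is reported, not enforced), keeps medium- and
weak-evidence intervals only over bases supported by at least two
technologies, and drops neutral evidence entirely. Conflicting regions are
then resolved: a gain base that orthogonal technologies call a loss, with
no orthogonal gain support anywhere, is removed; any same-type orthogonal
support retains the base even against opposite-type calls from another
technology. The published rule is stated for strong-evidence regions; the
package applies it to every retained interval, which only affects
medium/weak intervals that already carry two-technology support of their
own type and is therefore conservative. Finally, overlapping gain and loss
ends are trimmed: the orthogonally supported end keeps its coordinate and
the unsupported end recedes to abut it; if both or neither end is
supported the overlap is split at its midpoint (symmetric and
conservative; both tie-break outcomes are logged). Each benchmark interval
carries the median total copy number over the cohort's same-type
overlapping calls — a qualitative annotation, not a calibrated copy
number.

## Evaluation metrics

`precision_recall_f1()` compares a query call set to a benchmark per CNV
type as pure length ratios: precision is the fraction of the query's
affected length inside the benchmark, recall the fraction of the benchmark
recovered, F1 their harmonic mean. An empty side produces an `NA`
sentinel, never a silent zero, so a caller that fails to make any loss
call is visible as such. `pairwise_jaccard()` builds the
caller-by-replicate concordance matrices at segment, gene, or exon level
(the latter two after restricting both sides to an annotation track).
`estimate_ploidy()` is the length-weighted mean copy number over called
segments, and `recenter_shift()` is the log2(2 / ploidy) shift that moves
a median-centered caller's neutral level back to zero — −0.51 at the
study genome's ploidy of 2.85.

## The synthetic cohort generator

The generator exists so that every pipeline stage is testable without the
original sequencing data. It emulates, at segment level:

* **Truth landscapes** (`simulate_truth()`): each chromosome is tiled
  exactly (no gaps or overlaps) with segments of mean length 1.5 Mb
  (minimum 0.2 Mb); segments are typed gain (CN 3–5), loss (CN 1),
  copy-neutral LOH, or neutral, with the gain fraction chosen so the
  expected length-weighted ploidy matches the 2.85 target. Because the
  shuffled assignment ignores lengths, a deterministic greedy pass swaps
  neutral and gain assignments until the expected ploidy is within 0.1 of
  the target; the realized ploidy then varies only through the gain
  copy-number draw and stays within about ±0.3.
* **Caller noise** (`simulate_callset()`): per-type detection sensitivity
  (default 0.95), a minimum detectable length (50 kb), rounded Gaussian
  breakpoint jitter (SD 10 kb, clamped to the chromosome), Poisson false
  segments (1 per 100 Mb), and the ploidy mis-centering pathology — with
  some probability a replicate's copy numbers all shift by an integer
  offset and are re-typed, converting neutral segments to gains en masse.
  Emission randomness is drawn for every truth segment before filtering,
  so lowering sensitivity removes calls without re-randomizing the
  survivors; per-caller recall is monotone in sensitivity by
  construction.
* **Orthogonal technologies** (`simulate_orthogonal()`): the same channel
  without the ploidy failure, with tighter jitter (2 kb) and higher
  sensitivity (0.98), standing in for array and optical-mapping
  resolution limits.

RNG streams are derived by a stable FNV-1a hash of (seed, caller, center,
replicate), so adding a caller or technology never perturbs existing
streams and reruns are byte-identical. The default genome is three
chromosomes of 30/20/10 Mb, which keeps a full 126-call-set cohort run in
the tens of seconds; the noise defaults are the package's own (the study
does not characterize its callers' noise quantitatively) and are chosen
to reproduce the qualitative failure modes reported for real callers:
high replicate concordance for well-behaved callers, and genome-wide
excess gains with depressed cross-caller Jaccard for a ploidy-confused
one. The generator does not model read-level effects, tumor purity, or
coverage titration; sensitivity presets are the only knob for those, so
passing tests demonstrate the integration logic, not caller performance
on real libraries.

## What a default run looks like

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(out_dir = "run1", seed = 1)
res <- run_pipeline(cfg)
res$benchmark[1:3, ]
```

The run writes, under `out_dir`: the truth segment table, one scored
table per CNV type (disjoint intervals with per-caller converted scores,
total score, confidence), the validation table, the benchmark as TSV and
as VCF (symbolic `<DUP>`/`<DEL>`/`<LOH>` alleles, 1-based `POS`, `END`,
confidence and median copy number in `INFO`), per-call-set evaluation
metrics, the effective configuration, and a run log. Outputs carry no
timestamps, so a rerun with the same configuration is byte-identical.

## Limitations

The published headline numbers for the real cell line (346 gain, 33 loss,
320 LOH benchmark calls spanning roughly 1526 / 88 / 1490 Mb) require the
126 real WGS call sets and are not reproducible from simulation; the
package reproduces the rules — scoring tables, confidence scales,
validation arithmetic, re-centering — exactly, and demonstrates recovery
of simulated truth under controlled noise. Breakpoints in any such
benchmark remain best estimates, and the median copy numbers attached to
benchmark intervals should not be treated as a copy-number gold standard.
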