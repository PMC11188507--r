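# cnvconsensus

Build high-confidence somatic copy-number variation (CNV) benchmark sets
from many caller-by-replicate call sets on a hyper-diploid cancer genome,
validate them against orthogonal technologies, and evaluate callers
against the result.

## Who this is for

Groups benchmarking somatic CNV callers face two problems: no single
caller is trustworthy enough to define truth, and on aneuploid genomes
(overall ploidy far from 2, e.g. the HCC1395 cell line at ≈ 2.85) callers
that anchor the copy-neutral level on the genome median produce
genome-wide artifact gains or losses. `cnvconsensus` implements a
reproducibility-weighted consensus over a cohort of call sets, per-base
orthogonal validation, and length-based evaluation metrics, plus a
synthetic cohort generator so the whole pipeline is testable without any
sequencing data.

## The method in brief

Calls are typed from total copy number *c*: **gain** (*c* > 2), **loss**
(*c* < 2), **LOH** (*c* = 2 with minor allele 0). For each type, the
typed regions of all call sets are partitioned into disjoint intervals
annotated with which call sets support them (the BedTools `multiinter`
operation, reimplemented on `GRanges`). Replicate support per caller is
aggregated over five replicate groups — three triplicate centers, one
nine-replicate center down-weighted by 3, and three pooled singleton
centers — giving a cumulative score in [0, 15] that converts to a 0–3
scale (10–15 → 3, 7–9 → 2, 4–6 → 1, 0–3 → 0). The six callers' converted
scores sum to a total in [0, 18] mapped to confidence levels: 11–18
**strong**, 8–10 **medium**, 4–7 **weak**, 1–3 **neutral** (LOH, called
by five callers, uses its own scale with strong strictly above 8).

The benchmark keeps strong intervals unconditionally and medium/weak
intervals only over bases validated (same type, per base) by at least two
of the orthogonal technologies; neutral intervals are dropped. Gain/loss
conflicts against orthogonal evidence are resolved per base, overlapping
breakpoints are trimmed toward the orthogonally supported end, and each
interval carries the median copy number over the supporting cohort calls.

Evaluation is purely length-based: precision = |query ∩ benchmark| /
|query|, recall = |query ∩ benchmark| / |benchmark|, F1 their harmonic
mean; pairwise concordance is the Jaccard index of region sets, at
segment, gene, or exon level. `estimate_ploidy()` computes the
length-weighted mean copy number Σ lᵢcᵢ / Σ lᵢ, and `recenter_shift()`
the log2(2 / ploidy) correction for median-centered callers (−0.51 at
ploidy 2.85).

## Worked example

A full simulated study — hyper-diploid truth landscape, 6 callers × 21
replicates (126 call sets), 3 orthogonal technologies — scored, validated
and benchmarked:

```r
library(cnvconsensus)

truth <- simulate_truth(seed = 1)
truth
#> <truth_profile> 40 segments on 3 chromosomes, ploidy 2.999
round(recenter_shift(truth$ploidy), 2)
#> [1] -0.58

ch     <- simulate_cohort(truth, default_caller_models(seed = 1))
techs  <- simulate_orthogonal_set(truth, default_orthogonal_models(seed = 1))
scored <- score_cohort(ch, "GAIN")
table(scored$confidence)
#>    NONE NEUTRAL    WEAK  MEDIUM  STRONG
#>     251     274     303     228    2732

validation_table(scored, techs)[, c("confidence", "collapsed_mb", "ge1_pct", "ge2_pct")]
#>   confidence collapsed_mb ge1_pct ge2_pct
#> 1     STRONG     34.00223  99.971  99.902
#> 2     MEDIUM      0.04356  40.255   7.791
#> 3       WEAK      0.06875   4.758   0.000
#> 4    NEUTRAL      0.08396   0.000   0.000

bench <- assemble_benchmark(list(GAIN = scored), techs, ch)
head(bench[, 1:6], 3)
#>   chrom    start      end cnv_type confidence median_cn
#> 1  chr1      853  3086392     GAIN     STRONG         4
#> 2  chr1  3448849  9495894     GAIN     STRONG         4
#> 3  chr1 10337423 11682457     GAIN     STRONG         5

precision_recall_f1(bench, truth, "GAIN")
#> precision 0.9993  recall 0.9998  F1 0.9996 (query 34.01 Mb, truth 33.99 Mb, overlap 33.98 Mb)
```

Reading across the numbers: intervals supported by nearly all replicates
and callers (total score ≥ 11) are strong evidence and make up almost all
of the called gain length; the thin medium/weak/neutral strata are
boundary slivers and false calls, which either carry ≥ 2-technology
support or are dropped. The assembled benchmark recovers the simulated
truth to within a fraction of a percent by length. `run_pipeline()` wraps
these stages and writes every intermediate as TSV (plus the benchmark as
a symbolic-allele VCF) into an output directory, byte-identically across
reruns of the same configuration.

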