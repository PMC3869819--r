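---
title: "Methods: pooled-amplicon mutation discovery with scamprSeq"
author: "scamprSeq authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled-amplicon mutation discovery with scamprSeq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scamprSeq)
```

# Scope

scamprSeq implements SCAMPRing-style mutation discovery for TILLING
populations: rare induced point mutations are detected by deep amplicon
sequencing of overlapping DNA pools, and the identity of the carrier line is
recovered combinatorially from which pools show the variant. The package
covers the pooling design, a generative simulator used for validation, an
mpileup-to-counts reader, the statistical caller, PARSESNP-style effect
annotation, and population-level screen statistics.

# Tri-dimensional pooling

A population of 384 lines is arrayed on four 96-well plates. Twelve pools of
96 lines each are formed along three orthogonal dimensions:

* four **column pools** (column blocks 1–3, 4–6, 7–9, 10–12 across plates,
  with a per-plate rotation so each plate contributes a different block),
* four **row pools** (row pairs AB, CD, EF, GH, likewise rotated),
* four **plate pools** (one per plate).

Each line belongs to exactly one pool per dimension. A variant present in one
line therefore appears in exactly three pools — one per dimension — and that
triple intersects in a set of **six** candidate wells (two rows × three
columns on one plate), which are Sanger-validated. `validateDesign()` checks
this property by brute force over all 64 triples. The layout is data, not
code: designs are stored as JSON pool-membership maps, so alternative
rotations register via `registerScheme()` without code changes.

# Signal model

With 96 diploid lines per pool there are 192 allele copies. A heterozygous
mutation contributes 1/192 ≈ 0.52% of reads at its position; a homozygous
mutation 2/192 ≈ 1.04%. Sequencing error after base-quality filtering is of
order 0.05%, so the het signal sits roughly an order of magnitude above
noise at depth ~5,000×. Homeologous or paralogous SNPs — fixed differences
between subgenomes co-amplified by the primers — appear at high frequency
(~50%) in *every* pool and are separated from induced mutations by that
signature, not by frequency alone.

# Statistical caller

For each pool, reference base and substitution type, the background is the
empirical mean $\bar x$ and standard deviation $s$ of the alternate-allele
frequency over all *other* positions with the same reference base in that
pool (leave-one-out, so the tested position never contaminates its own
null). A candidate frequency $f$ at filtered depth $d$ is scored with a
one-sided prediction-interval $t$ statistic:

$$ t = \frac{f - \bar x}{s' \sqrt{1 + 1/n}}, \qquad s' = \max\!\left(s,\ \frac{1}{2d}\right), \qquad \text{df} = n - 1, $$

where $n$ is the number of background positions. The floor $1/(2d)$ prevents
a degenerate statistic when the background is all-zero; it equals half a
read's worth of frequency.

Calling is **two-stage**. A position/substitution in a pool is *positive*
when all of the following hold:

1. filtered depth ≥ `minDepth` (default 100),
2. $f \ge$ `minAltFreq` (default $1/(4 \cdot \text{poolSize}) = 1/384$,
   half the expected heterozygote signal),
3. one-sided $p \le \alpha$ (default 0.05).

The frequency screen is what controls false positives: at ~4,800
pool-position tests per amplicon, a raw $p \le 0.05$ rule alone would admit
dozens of background fluctuations; requiring the signal to reach half the
expected het fraction first restricts the $t$-test to its verification
role. A **candidate** then requires positives in at least one pool of each
of the three dimensions whose triple decodes to a nonempty well set;
positives in extra pools set a `review` flag rather than silently dropping
the call. Before candidate logic, positions where the alternate frequency is
≥ 0.2 in ≥ 90% of pools are classified as homeologs and excluded. EMS
consistency (G→A or C→T on the reference strand) is annotated on every
candidate and can be made a hard filter with `emsOnly = TRUE`.

# Simulator

`simulatePopulation()` plants mutations in a virtual population:
per-line mutation counts are Poisson with mean `density × kb` (or an exact
total via `nMutations`), positions uniform, 99% of substitutions G/C→A/T
(`spectrumFraction`), and a heterozygous fraction of 317/432 matching the
observed zygosity split. Homeolog positions receive alternate alleles in
all lines at `homeologFreq`. `simulatePoolCounts()` draws per-pool,
per-position base counts from a multinomial at the target depth, mixing
carrier allele fractions with a uniform error rate. Randomness is
deterministic given `seed`: each pool consumes its own derived stream
(`(seed*1009 + j) mod 2^31-1`), so counts for pool *j* do not depend on how
many other pools are simulated.

The simulator validates the caller; it is not a sequencing-artifact model.
It omits PCR jackpotting, strand bias, position-dependent error, alignment
artifacts and indels — its error is i.i.d. uniform across the three
non-reference bases. Recovery rates measured on it are therefore an upper
bound for real libraries.

# Pileup parsing

`countsFromPileup()` consumes samtools-mpileup text directly: `^X` (skip the
mapping-quality byte), `$`, indel runs `±n[ACGTN]+`, `.`/`,` as reference,
case-collapsed base calls; `*`, `N`, `>` and `<` are excluded from both the
counts and the filtered depth. Base qualities are Phred+33 and a call is
kept only when quality is **strictly greater** than `minBaseQuality`
(default 20). The parser is hand-written because no installed package parses
mpileup text; its output is tested for exact agreement with the simulator's
ground-truth counts round-tripped through fixture files.

# Effect annotation

`annotateEffect()` classifies substitutions against a `GeneModel` (exons,
CDS bounds, strand) using `Biostrings::GENETIC_CODE`: the first and last two
bases of each intron are **splice**, stop gains **nonsense**, amino-acid
changes **missense**, synonymous changes **silent**, everything else
**noncoding**. Reporting groups follow the established convention:
{nonsense, splice} are reported together, as are {silent, noncoding}.
Reverse-strand models translate the reverse complement; annotation is
invariant under constant coordinate shifts (tested).

# Screen statistics and numerical choices

`mutationDensity()` uses screened bp = lines × (amplicon − 200 bp), the 200
excluding low-coverage amplicon edges, and prints kb-per-mutation as a
"1/N" label with N the nearest integer. `aggregateDensity()` pools screened
bp over all amplicons before dividing (never averages per-amplicon
densities) and projects mutations per genome at a user-supplied genome size
(default 1,132 Mb). `screenBookkeeping()` reports — without reconciling —
any discrepancy between histogram assignments and unique mutation counts.

The $t$ tail probability uses `stats::pt(..., lower.tail = FALSE)` and is
unit-tested against independent numerical integration of the $t$ density to
1e-10. Multinomial draws use `stats::rmultinom`; Poisson counts
`stats::rpois`. Percentages are reported to one decimal place; density
labels to the nearest integer.

# Design decisions and limitations

* **Bioconductor shape.** `PoolCounts` extends `SummarizedExperiment`
  (assays `A`, `C`, `G`, `T`, `depth`; row metadata amplicon/pos/ref), so
  standard subsetting and accessors apply. `PoolingDesign` and `GeneModel`
  are S4 with validity methods.
* **Thresholds are fixed up front.** `minAltFreq`, `alpha`, `minDepth`, the
  homeolog thresholds and the simulator defaults encode the study
  conditions; they are parameters, not tuned values.
* The caller assumes the full 12-pool design is present and errors
  otherwise; partial designs are out of scope.
* Indels are counted in the spectrum but not called from pool counts; the
  pileup reader deliberately drops indel evidence.
* No empirical result is claimed beyond what `tests/` and
  `scripts/acceptance.R` compute.

# Worked example

```{r example}
design <- buildDesign()
params <- simParams(depth = 5000L, errorRate = 5e-4, seed = 42L)
amp <- c(bn1 = paste(sample(c("A","C","G","T"), 800, TRUE), collapse = ""))
truth <- simulatePopulation(amp, params, nMutations = 5L)
counts <- simulatePoolCounts(truth, design, params)
cand <- callCandidates(counts, design)
cand[, c("pos", "ref", "alt", "pools", "nLines", "emsConsistent")]
```
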