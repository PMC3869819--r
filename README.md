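# scamprSeq

Rare mutation detection in pooled amplicon sequencing of mutagenized
(TILLING) populations, including allopolyploids.

## The problem

TILLING screens chemically mutagenize a population (typically with EMS,
which induces almost exclusively G/C→A/T transitions) and then look for
lines carrying a mutation in a gene of interest. Screening thousands of
lines individually is expensive, so lines are pooled and the pools are
deep-sequenced: a mutation carried by one line out of many must be found as
a small excess of one alternate base at one position, and the carrier must
then be identified without sequencing anyone individually.

scamprSeq implements the full workflow: a tri-dimensional pooling design, a
statistical caller for sub-percent allele frequencies, combinatorial
decoding of positive pools back to candidate wells, effect annotation, and
the population statistics used to characterize a screen. A seeded simulator
generates pooled base counts with known ground truth for end-to-end
validation. In allopolyploids such as *Brassica napus*, homeologous SNPs —
fixed differences between co-amplified subgenome copies — are discriminated
from induced mutations by their presence at high frequency in every pool.

## Core model

384 lines on four 96-well plates are combined into 12 pools of 96 along
three orthogonal dimensions (4 column-block pools, 4 row-pair pools, 4
plate pools). Each line lies in exactly one pool per dimension, so a true
mutation appears in exactly **three pools**, and that triple intersects in
**six wells** on one plate.

With 96 diploid lines per pool, one heterozygote contributes

```
f_het = 1 / (2 × 96) = 1/192 ≈ 0.5%
```

of the reads at its position (a homozygote 2/192 ≈ 1%), against a
post-filter sequencing error of order 0.05%. Each pool/position/substitution
is scored against an empirical background — the mean x̄ and standard
deviation s of that substitution's frequency over all other same-reference
positions in the same pool — with a one-sided prediction-interval t
statistic:

```
t = (f − x̄) / (s′ √(1 + 1/n)),   s′ = max(s, 1/(2·depth)),   df = n − 1
```

A pool is positive when depth ≥ 100, f ≥ 1/384 (half the het signal) and
p ≤ 0.05; a candidate requires positives in all three dimensions whose
triple decodes to a nonempty well set. Positions at ≥20% frequency in ≥90%
of pools are classified as homeologs, not candidates.

## Worked example

```r
library(scamprSeq)
design <- buildDesign()                      # 12 pools × 96 lines, 384 lines
params <- simParams(depth = 5000L, errorRate = 5e-4, seed = 42L)
set.seed(11)
amp <- c(bn1 = paste(sample(c("A","C","G","T"), 800, TRUE), collapse = ""))
truth  <- simulatePopulation(amp, params, nMutations = 5L)
counts <- simulatePoolCounts(truth, design, params)
counts
#> class: PoolCounts
#> dim: 800 12
#> assays(5): A C G T depth
#> colnames(12): 1 2 ... 11 12

cand <- callCandidates(counts, design)
cand[, c("pos", "ref", "alt", "pools", "lines", "pooledFreq")]
#>   pos ref alt  pools                                     lines  pooledFreq
#> 1 184   G   A 1,6,12       P4:C1,P4:C2,P4:C3,P4:D1,P4:D2,P4:D3 0.001550000
#> 2 608   G   A  4,5,9 P1:A10,P1:A11,P1:A12,P1:B10,P1:B11,P1:B12 0.002933333
#> 3 736   G   A 3,6,10       P2:C7,P2:C8,P2:C9,P2:D7,P2:D8,P2:D9 0.001783333
#> 4 744   G   A  1,7,9       P1:E1,P1:E2,P1:E3,P1:F1,P1:F2,P1:F3 0.001316667
#> 5 775   C   T 1,5,12       P4:A1,P4:A2,P4:A3,P4:B1,P4:B2,P4:B3 0.001600000
```

All five planted mutations are recovered; each decodes to six wells
containing the true carrier (e.g. the mutation at position 184, planted in
line `P4:D3`, is positive exactly in pools `poolsForLine(design, "P4:D3")`
= 1, 6, 12). The homozygote at 608 shows roughly twice the pooled frequency
of the heterozygotes, as expected from the allele arithmetic above.

A command-line front end is installed at `inst/exec/scampr` with
subcommands `design`, `simulate`, `counts`, `call`, `annotate`, `stats` and
`run`.

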