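# orcall

Stringent receptor-expression calling and developmental staging for
single-cell RNA-seq of olfactory sensory neurons.

## The problem

Each mature olfactory sensory neuron in the mouse expresses one — and only
one — of the >1,000 olfactory receptor (OR) genes. Probing that
*one-neuron-one-receptor* rule across the whole OR repertoire with
single-cell RNA-seq is hard for reasons that have nothing to do with
sequencing depth: a strongly expressed OR drops mismapped reads onto its
homologs, genomic DNA contaminates libraries, and truncated non-coding
transcripts masquerade as expression. `orcall` is for analysts who want the
full stringent pipeline behind the key developmental observation — that
*immature* neurons transiently express several ORs (on average ~2.9, range
2–9) at reduced total levels, while the rule is restored in mature neurons —
as reusable, tested R functions.

The package covers four stages, plus a synthetic-data generator that makes
all of them testable without raw sequencing data:

1. **Receptor calling** from alignments. A receptor in a cell is
   `confident` only if (i) its CDS is completely covered (depth ≥ 1 at
   every coding base), (ii) the high-MAPQ read fraction is ≥ 0.8
   (MAPQ ≥ 30), and (iii) some read spans an annotated intron exactly.
   Meeting 1–2 criteria gives `uncertain`, none gives `absent`; cells
   become `none` / `single` / `multi` / `undetermined`.
2. **Quantification**: TPM with small-RNA exclusion *before* per-cell
   rescaling to 10⁶, and detected-gene counts at the strict 1-TPM
   threshold.
3. **Staging**: per-gene rank transform across cells, PCA on 44 annotated
   marker genes (oriented so mature cells score high on PC1), 3-way
   classification into mature / immature / other, plus the data-driven
   marker selection from a two-condition bulk FPKM table
   (FPKM > 100, top 100 per direction by pseudocounted fold change).
4. **Statistics**: two-sided Fisher exact tests (point-probability
   convention, `p = Σ {P(T) : P(T) ≤ P(T_obs)}` over fixed-margin tables),
   exact/approximate Wilcoxon rank-sum tests, proportions with binomial
   standard errors `100·√(p(1−p)/n)`, and a report object assembling every
   contingency table linking stage, age and receptor status.

The generator emits valid GTF gene models (receptors with spliced upstream
exons and homolog groups), per-cell SAM alignments (uniform high-MAPQ
transcript tiling for true expression, low-MAPQ narrow decoy piles for
homolog mismapping, unspliced scatters for genomic contamination), and a
dropout-aware abundance matrix (reliable detection above 10³ TPM,
dropout-dominated below 10², log-linear in between) with full ground truth.

## Worked example

```r
library(orcall)
cfg <- orSimConfig(seed = 1, nCells = 300)   # study-condition defaults
res <- runPipeline(cfg)

res$truth
#> CohortTruth with 300 cells
#>          stage
#> age       immature mature other
#>   adult         11     75    10
#>   newborn       82     53    69
#> receptor-positive: 181 (multi: 37; mean receptors per multi cell 3.14)

head(subset(res$calls, status == "confident"), 4)
#>     cell_id  gene_id       tpm cds_covered mapq_fraction spliced_ok    status
#> 1 cell_0001 Olfr0042  5434.738        TRUE     0.9512195       TRUE confident
#> 3 cell_0002 Olfr0190  2538.933        TRUE     0.9729730       TRUE confident
#> 4 cell_0004 Olfr0050 11427.482        TRUE     0.9534884       TRUE confident
#> 6 cell_0005 Olfr0054 16080.347        TRUE     0.9523810       TRUE confident

print(res$report)
#> == stage x age ==
#>           
#>            adult newborn
#>   immature    11      82
#>   mature      75      53
#> immature:mature ratio  adult 0.15 : 1, newborn 1.55 : 1
#> Fisher two-sided p = 3.6e-13
#>
#> == receptor status x age (single/multi cells) ==
#>         
#>          adult newborn
#>   multi      7      30
#>   single    64      64
#>   adult: multi (10 +/- 4)%
#>   newborn: multi (32 +/- 5)%
#> Fisher two-sided p = 0.00068
#>
#> == receptor status x stage (single/multi cells) ==
#>         
#>          immature mature
#>   multi        36      1
#>   single       27    101
#>   immature: multi (57 +/- 6)%
#>   mature: multi (1 +/- 1)%
#> Fisher two-sided p = 4.9e-18
#>
#> == detected genes ==
#> by age: medians adult 2777, newborn 2788 | Wilcoxon p = 0.11
#> by status: medians multi 2773, single 2774 | Wilcoxon p = 0.53
#>
#> total receptor TPM: median single 2.14e+04, multi 2.3e+04 | Wilcoxon p = 0.59
#> receptors per multi cell: mean 3.14, median 2.0, range 2-8 (n = 37)
```

Reading the report: newborn cohorts are immature-rich (here 1.55:1 vs 0.15:1
in adults; the configured study ratios are 1.45:1 and 0.13:1), the
multi-receptor state concentrates overwhelmingly in immature neurons (57% vs
1% of receptor-positive cells, Fisher p ≈ 5e-18), multi cells carry ~3
receptors on average, and detected-gene counts (~2.8e3 per cell above 1 TPM)
do not differ by age or status — the simulated cohort reproduces the
qualitative and quantitative structure the analysis was built to detect.

Individual steps are available separately: `generateGeneModels()`,
`simulateCohort()`, `simulateExpression()`, `simulateAlignments()`,
`computeTpm()`, `callReceptors()`, `classifyCells()`, `rankTransform()`,
`markerPca()`, `classifyStage()`, `selectMarkersFromBulk()`,
`fisherExactTwoSided()`, `wilcoxonRankSumTwoSided()`, `proportionWithSe()`,
`buildReport()`; file interchange via `writeGtf()`/`readGtf()`,
`writeSam()`/`readSam()`, `writeMatrixTsv()`/`readMatrixTsv()`.

See the methods vignette (`vignettes/receptor-calling-methods.Rmd`) for the
model, the conventions that had to be fixed, and known limitations.

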