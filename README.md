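# aleSplice

Quantify **alternative last exon (ALE) usage from splice-junction read
counts** and ask what distinguishes tumors at the extremes of the isoform
ratio. The motivating case is the *KRAS* locus: splicing to *KRAS4B* skips
exon 4A, while *KRAS4A* includes exons 4A and 4B, so three junctions fully
describe the event — exon 3→4A (`inc1`), exon 4A→4B (`inc2`) and the
skipping junction exon 3→4B (`exc`). The package is aimed at analysts who
start from junction quantifications (STAR `SJ.out.tab` files or
Xena/TCGA-style junction matrices) rather than raw reads.

## The statistics at the core

For each sample, the **exon inclusion score**

$$\psi = \frac{(inc_1 + inc_2)/2}{(inc_1 + inc_2)/2 + exc}$$

estimates the fraction of the gene's transcripts that use the inclusion
isoform; the two inclusion junctions are averaged because each inclusion
transcript contributes both. Samples with fewer than 20 `exc` reads are
flagged out (low coverage makes $\psi$ artificially unstable); no limit is
placed on the inclusion counts, since near-zero inclusion is biologically
real. The **isoform ratio** $(inc_1+inc_2)/2 \,/\, exc = \psi/(1-\psi)$
ranks samples identically to $\psi$.

Downstream, the package stratifies samples into high/low ratio extremes of
explicit sizes, ranks genes between the groups by a signal-to-noise
statistic $s = (\mu_{low}-\mu_{high})/(\sigma_{low}+\sigma_{high})$ with
GSEA-style variance floors, and tests gene sets two ways, both implemented
from scratch:

* **weighted Kolmogorov–Smirnov enrichment** (GSEA running sum, weight
  $p=1$ by default) with a seeded permutation null, normalized enrichment
  scores and Benjamini–Hochberg FDR;
* **hypergeometric over-representation** of the top-*k* (default 100)
  between-group genes, conditioned on the measured-gene universe.

A seeded synthetic-cohort generator (negative-binomial coverage, binomial
read allocation, planted expression signature in low-inclusion samples)
provides ground truth for recovery and null-calibration studies; see the
methods vignette (`vignettes/ale-inclusion-methods.Rmd`) for the model.

## Worked example

```r
library(aleSplice)

cfg    <- simulationConfig(seed = 7)        # 60 tumors, 30% KRAS-mutant
sim    <- simulateJunctions(cfg)
expr   <- simulateExpression(cfg, sim$truth)
scored <- scoreEvent(sim$event, sim$counts)
head(as.data.frame(scored), 3)
#>       sample inc1 inc2 exc       psi     ratio pass_filter
#> S0001  S0001   33   61 126 0.2716763 0.3730159        TRUE
#> S0002  S0002   83   62 216 0.2512998 0.3356481        TRUE
#> S0003  S0003   44   41  77 0.3556485 0.5519481        TRUE

cmp <- compareMutantWt(scored, as.data.frame(sim$annotation))
sprintf("mutant/WT inclusion fold change %.2f (rank-sum p = %.2g)",
        cmp$fold_change, cmp$p_two_sided)
#> "mutant/WT inclusion fold change 2.23 (rank-sum p = 5.3e-09)"

ratios <- setNames(ifelse(scored$pass_filter, scored$ratio, NA),
                   scored$sample)
groups <- stratifyByRatio(ratios, nHigh = 15, nLow = 15)
ranked <- rankGenes(expr, groups)        # positive = up in low-ratio group

set.seed(42)
gsc <- GeneSetCollection(c(
    list(CELL_CYCLE_LIKE = sprintf("G%04d", 1:50)),   # the planted set
    setNames(lapply(1:10, function(i)
        sample(sprintf("G%04d", 51:1000), 40)), sprintf("RANDOM%02d", 1:10))))
enr <- runEnrichment(ranked, gsc, nPerm = 1000, seed = 1)
head(enr[order(enr$p_perm), c(1:6)], 3)
#>         set_name size         es        nes      p_perm    q_value
#>  CELL_CYCLE_LIKE   50  1.0000000  2.1842464 0.001069519 0.01176471
#>         RANDOM08   40 -0.2962616 -1.1680215 0.287500000 0.98177921
#>         RANDOM03   40 -0.2604005 -0.9878194 0.425287356 0.98177921
```

The per-sample table shows the three junction counts, the inclusion score
and ratio, and the coverage-filter flag. The mutant/wild-type comparison
recovers the simulated +1.5-logit inclusion shift. The planted
`CELL_CYCLE_LIKE` signature tops the enrichment table with the maximal
running-sum score (`es = 1`: all 50 member genes lead the low-vs-high
ranking), while the random sets stay at chance.

`runPipeline()` chains these stages from files on disk and writes
`inclusion.tsv`, `groups.tsv`, `ranked.rnk`, `enrichment.tsv`, `ora.tsv`,
`compare.tsv` and a run manifest; `inst/scripts/ale-pipeline.R` is a thin
command-line wrapper with `simulate` and `run` subcommands.

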