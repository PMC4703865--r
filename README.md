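# pausekit

Downstream analysis of RNA polymerase II ChIP-seq for studies of
promoter-proximal pausing and pause release. Given aligned,
deduplicated read coordinates (BED; one library per condition ×
antibody mark, plus matched inputs) and a GTF annotation, pausekit
computes window-based read densities, pausing indices and their change
between conditions, classifies transcriptionally activated
(pause-released) genes, calls enrichment peaks against input, builds
TSS-centred profile matrices, and performs cohort-level bootstrap
inference. A synthetic read simulator with closed-form expected values
provides a ground-truth test bed for the whole pipeline.

## The statistics

For each gene a single primary transcript (maximal gene-body read
density) defines three strand-aware windows about its TSS:
TSS-proximal `[TSS−150, TSS+150)`, gene body `+250 → 3′ end`, and a
`(−2000, +2500)` flank for profiles. With all libraries linearly scaled
to the depth of the smallest (factor `min(totals)/total ≤ 1`), the
**pausing index** of a gene is

```
PI = (TSS-proximal read density) / (gene-body read density)   [reads/bp over reads/bp]
```

Genes must exceed a body density of 0.05 reads/bp (in at least one
condition under comparison); a gene is **activated** when
`PI(baseline)/PI(induced) > 2`, i.e. its pausing index drops by at
least 50 % upon induction. Cohort effects (PI ratios, percent occupancy
changes, mean body coverage depth) are tested by a bootstrap:
10⁵ resamples per group, effect size = difference of resampled medians,
centred 95 % empirical confidence interval, one-sided empirical P =
fraction of resampled effects on the wrong side of zero. Peaks are
called in 500-bp sliding windows at ≥ 4-fold enrichment over a
depth-matched input with a Poisson upper-tail p-value controlled by
Benjamini–Hochberg at FDR 0.001.

## Worked example

```r
library(pausekit)

# simulate a serum-induction study: 100 genes, half released 3-fold on
# induction, plus an arm where release is pharmacologically blocked
ds <- simulate_contrast(tempfile("demo"),
                        conditions = c("S0", "S15", "S15+NU7441"),
                        marks = c("PolII", "gH2AX"),
                        n_genes = 100, frac_activated = 0.5, seed = 7)

cfg <- contrast_config(ds$sheet, ds$annotation,
                       inhibitor_condition = "S15+NU7441",
                       n_boot = 1e4, seed = 7)
res <- run_contrast(cfg)
#> 100 genes pass the density filter; 50 activated (PI ratio > 2)

length(res$activated)
#> [1] 50
median(res$contrast$pi_ratio[res$contrast$activated])
#> [1] 2.937446
res$effects$gH2AX_body_density
#> Bootstrap difference-of-medians effect size
#>   effect (median A - median B): 0.117474
#>   95% empirical CI: (0.114671, 0.121159)
#>   one-sided empirical P (greater): < 0.0001
#>   n_boot = 10000, n_A = 50, n_B = 50
```

Reading: the 50 genes designed as activated are recovered; their median
pausing-index ratio ≈ 2.9 matches the simulated 3-fold release; the
γH2AX gene-body density gain of ≈ 0.11 reads/bp on those genes (the
designed `λ_body (r − 1) × depth × scale`) is significant at the
bootstrap's resolution floor. Outputs land in `cfg$outdir`: a per-gene
TSV, cohort-statistics JSON, a TSS-centred profile matrix of activated
genes sorted by induced body occupancy, scaled bedGraph tracks and a
run log. `inst/scripts/pausekit-cli.R` wraps `make-fixtures` and `run`
for shell use.

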