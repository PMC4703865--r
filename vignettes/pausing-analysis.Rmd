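---
title: "Quantifying Pol II pause release from ChIP-seq window densities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Pol II pause release from ChIP-seq window densities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

At most metazoan genes, RNA polymerase II initiates and then halts
30–100 bp downstream of the transcription start site (TSS). Release of
this promoter-proximally paused polymerase into the gene body is a
regulated step of gene activation: upon a stimulus such as serum
induction, immediate-early genes shift occupancy from the TSS into the
transcribed region. ChIP-seq of Pol II (and of DNA-damage-response marks
such as γH2AX that track elongating polymerase) captures this shift as a
redistribution of read density.

pausekit implements the downstream half of such an experiment: it
consumes aligned, deduplicated read coordinates — one library per
condition × antibody mark, plus a matched input per condition — and a GTF
annotation, and produces per-gene pausing statistics, condition
contrasts, and cohort-level bootstrap inference.

## Windows and the pausing index

For every gene one primary transcript is selected and three strand-aware
windows are derived from its annotated TSS (all coordinates internally
0-based half-open; GTF is converted at the boundary):

* **TSS-proximal**: `[TSS − 150, TSS + 150)`, 300 bp, in transcript
  orientation. The interval notation "(−150, +150)" in the field's usage
  does not pin endpoint conventions; we fix the half-open form with the
  TSS at offset 150.
* **gene body**: +250 from the TSS to the transcript 3′ end. The 100-bp
  gap between windows excludes the shoulder of the paused peak.
* **flank**: `(−2,000, +2,500)` about the TSS, 4,500 bp, used for
  TSS-centred binned profiles and heat-map style matrices.

The **pausing index** (PI) of a gene is the ratio of TSS-proximal read
density to gene-body read density (reads per bp). High PI means paused;
a fold decrease of PI upon stimulation means pause release. The
**PI ratio** between a baseline A and an induced condition B is
`PI(A)/PI(B)`; values above 1 indicate release in B, and the activation
call `PI(A)/PI(B) > 2` is identical to "at least 50 % PI reduction".

Reads are counted into a window when the alignment interval overlaps it
by ≥ 1 bp; reads overlapping the annotated spans of more than one gene
are discarded outright (the single-gene rule), which keeps ambiguous
signal at gene pairs out of every window. The rule is enforced against
transcript spans, not flank windows — flanks reach into neighbours by
construction and would otherwise discard excessively.

Library-size differences are handled by linear down-scaling: every
library's counts are multiplied by `min(totals)/total ≤ 1` so effective
depths match the smallest library. Scaled counts are fractional by
design. Because the PI is a within-library density ratio, the scale
factor cancels; the implementation computes the PI from raw counts so
that this invariance is exact at the bit level rather than up to
round-off.

### Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| TSS half-width | 150 | bp | pause-peak capture window |
| body offset | 250 | bp | start of the elongation window |
| minimum body length | 200 | bp | genes shorter than offset+minimum are flagged and excluded from pausing statistics |
| body-density filter | 0.05 | reads/bp | removes low-occupancy genes where the PI is unstable |
| activation fold | 2 | — | PI-ratio threshold calling pause release |
| peak fold / FDR | 4 / 0.001 | — | enrichment gate parameters |
| bootstrap resamples | 100,000 | — | cohort inference resolution |

The 0.05 filter is intentionally arbitrary — it trades cohort size
against PI stability — and is applied under an "any condition under
comparison" policy by default: a gene silent at baseline but induced
afterwards is exactly the object of study, so an "all conditions" rule
(available as an option) would remove it.

## Primary transcripts and open choices

Where a gene has several transcripts, the one with maximal body read
density is kept. Two choices here were genuinely open:

* **Which library's density?** We average the scaled body densities of
  the two Pol II libraries of the contrast, so the selection is stable
  under relabelling of conditions. Ties break to the longer transcript,
  then the lexicographically smaller identifier.
* **Activation gate.** Whether activation should additionally require a
  gene-body count increase is ambiguous in the field's usage; both gates
  are implemented and the extra gate defaults off
  (`require_body_increase`).

## Peak calling

`call_peaks()` is a deliberately simple sliding-window caller (500-bp
windows every 100 bp): expected counts come from the depth-matched input
library, floored at the genome-wide mean input per window; candidates
need ≥ 4-fold enrichment and a Poisson upper-tail p-value significant
after Benjamini–Hochberg at FDR 0.001; adjacent candidates merge keeping
the best window's statistics. It is a stand-in for full-featured callers
(no local lambda, no fragment-model) sufficient for gating the gene
universe ("genes with a ChIP peak"); the gate defaults off for synthetic
runs, where the density filter already defines the universe, and can be
switched on with `use_peak_gate`.

## Bootstrap difference of medians

Cohort statistics are computed by resampling: each group (a per-gene
metric under two conditions, or in two treatment arms) is resampled with
replacement `n_boot` times from its own empirical distribution, the
effect size of each resample is the difference of medians, the centred
95 % empirical confidence interval is the (2.5, 97.5) percentile pair of
those effects (linear interpolation between order statistics), and the
one-sided empirical P for the null "effect is positive" is the fraction
of resampled effects ≤ 0 (ties included; the mirrored rule for the other
direction). P = 0 is stored as 0 and printed as `< 1/n_boot`, the
procedure's resolution floor; a `(k+1)/(n+1)` smoothed variant is
available by flag.

Resampling is deliberately **unpaired** — each group from its own
distribution, even when the genes are shared — matching the procedure
the cohort statistics are defined by; a paired variant
(`paired = TRUE`) exists for sensitivity analysis. Two numerical
details: resampling draws indices, not values, so adding a constant to
one group shifts the whole effect distribution by exactly that constant
(up to one ulp of float reassociation); and the two groups' RNG streams
are keyed to a canonical ordering of the group *data* rather than to
argument position, so swapping the groups yields the exactly negated
effect distribution — mirrored CI and p — under the same seed.

## The synthetic data generator

`sim_gene_panel()` and `simulate_library()` provide the ground-truth
test bed. Genes sit on one synthetic chromosome with 10-kb gaps,
alternating strands. Per gene and condition, Pol II reads are drawn as

* a TSS component: `Poisson(λ_tss · depth)` read starts from a normal
  distribution centred `peak_offset` bp downstream of the TSS (default
  50 bp, sd 30 bp — the promoter-proximal pause position), truncated to
  the TSS window;
* a body component: `Poisson(λ_body · body_length · depth · r)` starts
  uniform over the body, with `r` the gene's release factor under
  induction and 1 at baseline **and** under an inhibitor condition
  (release blocked); inhibitor conditions additionally multiply the TSS
  component by a retention factor (default 1.3), emulating TSS
  accumulation when initiation continues but release is blocked — a
  fixture parameter, not a claim about the biology's magnitude.

γH2AX-like marks are body-proportional only and are confined to
`[TSS − 150, transcript end)` by construction, emulating
transcription-coupled DDR signal that does not spread beyond transcript
boundaries. Input libraries are uniform background sequenced to a depth
matching the condition's Pol II library, so enrichment against input is
meaningful after depth scaling. All marks receive uniform genome-wide
background (default 0.01 reads/bp per unit depth).

The closed-form expected PI of a simulated gene,
`(λ_tss/300)/(λ_body · r)`, is the oracle for parameter-recovery tests.
The default study conditions are 200 genes, half activated with release
factor 3, `λ_tss = 300` reads and `λ_body = 0.25` reads/bp (so body
densities sit well above the 0.05 filter), read length 36, and
per-condition depth factors `{1, 1.25, 0.8}` so the scaling step is
always exercised.

What the simulator does **not** emulate: mappability and sequence
content (no FASTQ), fragment-length structure (read starts are drawn
directly; the analysis operates on interval overlap), overlapping gene
pairs (generated separately when the single-gene rule is the subject),
replicate structure, and any form of biological between-gene rate
heterogeneity beyond the designed activated/unactivated split. Passing
tests therefore demonstrate correctness of the quantification and
inference machinery under a known generative model — not robustness to
every artefact of real ChIP-seq.

## Worked example

```{r example, eval = FALSE}
library(pausekit)
ds <- simulate_contrast(tempfile("demo"),
                        conditions = c("S0", "S15", "S15+NU7441"),
                        marks = c("PolII", "gH2AX"),
                        n_genes = 100, seed = 7)
cfg <- contrast_config(ds$sheet, ds$annotation,
                       inhibitor_condition = "S15+NU7441",
                       n_boot = 1e4, seed = 7)
res <- run_contrast(cfg)
length(res$activated)          # pause-released genes
res$effects$pi_ratio           # control vs inhibitor PI-ratio effect
res$effects$gH2AX_body_density # DDR mark tracks release
```

The pipeline stages are individually callable
(`read_gtf_transcripts()`, `derive_windows()`, `assign_reads()`,
`window_density()`, `pausing_records()`, `pausing_contrast()`,
`bootstrap_effect()`), and all tables are plain data frames exportable
as TSV; coverage tracks export as bedGraph.

## Numerical and degenerate-input conventions

* Genes with flagged-empty bodies (transcript ≤ 450 bp at defaults) get
  `NA` densities and are excluded from pausing statistics, never errors.
* Windows clip at chromosome position 0; the TSS window is 300 bp and
  the flank 4,500 bp except under clipping.
* Percent occupancy change uses a pseudocount floor
  `max(A, 1 × scale_factor)` in the denominator, so genes unoccupied at
  baseline yield large finite changes rather than infinities.
* The Poisson tail is evaluated as `P(X ≥ k)` on raw IP counts with the
  expected value rescaled to the raw scale, avoiding the incorrect
  variance a test on scaled (fractional) counts would imply.
* Profile bins assign each read to the single bin containing its
  midpoint, so row sums track window counts without double counting.
* In tests, bootstrap problem sizes are scaled to the suite (n_boot
  2,000, 500 coverage replicates; the pipeline default stays at 10^5).

## Limitations

The peak caller is a simplified gate, not a general-purpose caller. The
single-gene rule uses only the selected primary transcript spans, so
reads shared by an unannotated antisense unit are not detected. No
per-gene hypothesis test is provided — inference is cohort-level by
design. Fragment extension is not performed; a config hook is reserved
should tag-extension ever matter for the window sizes used here.
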