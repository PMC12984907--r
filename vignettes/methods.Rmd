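---
title: "Methods: genomic alteration-based drug repurposing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genomic alteration-based drug repurposing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repurposeR)
```

## Overview

`repurposeR` nominates drug repurposing candidates from gene-level tumor
genomics. The workflow, run independently per patient stratum (e.g.
HPV-positive and HPV-negative head and neck cancer, whose driver landscapes
differ enough that pooling them hides subtype-specific signal), is:

1. **Copy-number analysis.** Call high-level amplifications (copy number
   > 4) and homozygous deletions (copy number = 0) per gene, test each
   gene's event count against the stratum's genome-wide background rate
   (binomial) and against a pooled-resampling permutation null, correct
   both p-vectors with Benjamini–Hochberg, and rank dual-significant genes
   by a GISTIC-like amplitude-times-frequency score.
2. **Mutation analysis.** Count non-synonymous events per gene, test the
   burden against a CDS-length-proportional binomial null and a multinomial
   permutation null, and rank dual-significant genes by a composite
   mutation score.
3. **Network expansion.** Expand the union of risk genes to immediate
   protein–protein interaction neighbors with combined score ≥ 700,
   retaining neighbor→seed provenance.
4. **Literature validation.** Clean an abstract corpus, extract
   gene-evidence sentences with a pluggable backend, and keep only risk
   genes and neighbors with independent literature support.
5. **Drug enrichment.** For every drug, test the overlap of its target set
   with the validated risk set by a right-tailed hypergeometric test over
   the druggable-gene universe and by resampling risk-set-sized gene sets;
   retain drugs significant in both after BH correction, classified as
   *direct* (targeting a risk gene), *indirect* (targeting a validated
   neighbor) or *both*.

## Statistical model

### Copy-number significance

For a gene with $x$ high-level events among $n$ samples, the parametric
p-value is the binomial upper tail

$$P(X \ge x) = \sum_{k=x}^{n} \binom{n}{k} p_0^k (1-p_0)^{n-k},$$

where $p_0$ is the fraction of *all* pooled copy-number observations in the
stratum beyond the high-level threshold. Using the cohort-wide pool as the
null means each gene is tested against the cohort's own genomic
instability: an unstable cohort requires more recurrent events for
significance. The permutation null redraws $n$ values with replacement from
the same pool 1000 times and counts threshold exceedances; the empirical
p-value is add-one smoothed,

$$p_{\mathrm{emp}} = \frac{1 + \#\{ \mathrm{count}_i \ge x \}}{N + 1},$$

so it is bounded below by $1/(N+1)$ and ties count as exceedances. Both
p-vectors are BH-corrected and a gene must pass both gates
($q < \alpha = 0.05$). The dual gate is deliberately conservative: the
parametric test brings power, the permutation test robustness to the
binomial's independence assumptions.

### GISTIC-like score

Amplification amplitude per altered sample is $\log_2(\min(\mathrm{CN},
7)) - 1$ — zero at the diploid baseline (the $\log_2(\mathrm{CN}/2)$
convention) and capped at copy number 7 so single outlier samples cannot
dominate genes with moderate amplitude but high frequency. Deletion
intensity is $+1$ for single-copy loss and $+2$ for homozygous deletion.
The score is the mean amplitude over altered samples times the high-level
event frequency in percent; for deletions the frequency term counts
homozygous deletions only. Two readings of the amplitude log rule both zero
at the baseline; `log2(CN) - 1` is the default because it stays finite at
copy number 1, and `log2(CN - 1)` is available via `log_rule`. Likewise the
amplitude-average denominator is not uniquely determined by the score's
verbal definition; the default averages over all altered samples
(`amplitude_scope = "altered"`), which keeps the amplitude term independent
of cohort size, with high-level-only accumulation available as a flag.

### Mutation burden

With $N$ total mutations in the stratum (synonymous included — they carry
no selection signal but calibrate the background rate) and gene-specific
probability $p_g = L_g / \sum_j L_j$ over CDS lengths of the annotation
universe, the parametric test is the binomial upper tail of the
non-synonymous count at $(N, p_g)$. The permutation null draws 10,000
multinomial cohorts of size $N$ over the universe, preserving the total in
every draw; each tested gene is compared with its marginal. A per-gene
binomial sampler is available (`null_method = "binomial"`) — the marginals
are identical in distribution, which a test verifies at 3 Monte-Carlo
standard errors, but draws are then independent across genes. The composite
`MutationScore` is mutations-per-bp times the percent of patients mutated;
frequency is expressed in percent (0–100) for symmetry with the
copy-number score (a global constant, so rankings are unaffected).

### Score cutoffs

Within dual-significant genes, a final score threshold separates the
upper tail from the bulk. Two rules are implemented: a percentile rule
(default: 95th percentile) and a knee rule (maximum perpendicular distance
from the chord of the sorted-score curve), since "natural breaks" in a
score histogram is not an algorithm. The reference distribution for the
cutoff is, by default, the scores of **all tested genes**
(`cutoff_scope = "all"`): the cutoff then marks where scores leave the
background bulk, and a tight cluster of genuinely altered genes is kept
intact. Restricting the reference to the dual-significant genes themselves
(`cutoff_scope = "significant"`) is supported but interacts badly with
small significant sets — the 95th percentile of ten similar scores retains
roughly one of them, discarding true signal on rank alone. A single
dual-significant gene is always retained: one observation defines no
distribution to threshold.

### FDR bookkeeping

Only genes with at least one high-level event (copy number) or one
non-synonymous mutation (burden) enter the BH correction; zero-event genes
have $p = 1$, carry no evidence, and are reported with `NA` q-values.
Counting them in $m$ would only dilute the correction: with 1000
permutations the empirical-p floor is $1/1001$, and at $m$ = all genes the
BH-adjusted floor for a handful of tied true positives can exceed
$\alpha$ mechanically, regardless of effect size.

## Network, literature and drug stages

The neighbor cutoff defaults to combined score ≥ 700 — the conventional
high-confidence band on the 0–1000 scale — with strict `>` behind a flag
(the two differ only at exactly 700). Expansion is one hop, score-gated
only, with no per-seed top-$k$ by default. Neighbors retain the set of seed
risk genes they connect to; that provenance drives the direct/indirect
classification and the Sankey-style reporting.

Literature validation ships a deterministic lexicon extractor: sentences
are segmented at `.!?` boundaries with abbreviation guards, and gene
symbols match as whole tokens, case-sensitively (`EGFR` never matches
inside `VEGFR`). Every evidence sentence must be a verbatim substring of
its abstract — backend output violating this is rejected — so any claimed
evidence can be relocated exactly. The extraction backend is an interface:
an LLM-based extractor can be plugged in as any function with the same
record-level contract, and the lexicon backend is what the tests use. The
corpus filter keeps publications from 2001 onward ("after the year 2000");
the support threshold defaults to one distinct article per gene
(`min_articles`), recorded in the output.

Drug enrichment takes the druggable universe to be every gene with at
least one interaction; the risk-set size $n$ is counted after intersecting
with that universe. The empirical test resamples risk-set-sized gene sets
uniformly from the universe — one shared ensemble across drugs per run —
guarding against enrichment driven purely by promiscuous targets. 100,000
permutations is the default: with $\approx 200$ drugs under BH, the add-one
floor of a smaller null (e.g. $1/2001$) can exceed the 0.05 gate for tied
top drugs purely mechanically, exactly the regime the large $N$ avoids.

## Synthetic data: what it emulates and what it does not

The generator produces all six input kinds with planted signal and known
truth. The default "demo cohort" is 500 genes × 100 samples: 10 amplified
genes at copy number 6 in 30% of samples, 5 homozygous-deleted genes in
30%, 5 mutation drivers at 10× their length-expected rate hitting at least
10% of patients, 2 planted high-score PPI neighbors per planted gene, 200
decoy drugs plus one planted drug targeting risk genes and one targeting
neighbors, and 500 abstracts mentioning every planted gene and neighbor
three times. The total mutation count (3300) matches a typical
head-and-neck cohort rate of roughly 33 somatic mutations per case. The
background copy-number distribution puts 97.2% mass at the diploid value
and 0.4% on each other state in 0–7 so background event rates are
non-degenerate. Planted drivers are guaranteed their minimum patient
fraction in non-synonymous events — the analysis counts hits through
protein-altering mutations only, so a plant that were allowed to come out
mostly Silent would not be the stated condition.

Deliberately *not* emulated: segment-level copy-number structure, GC or
purity artifacts, trinucleotide mutation signatures, expression-covariate
mutation rates, realistic PPI topology (background edges are Erdős–Rényi
and never reach the 700 cutoff), and natural-language variability in
abstracts. Passing the planted-recovery tests therefore demonstrates that
the statistical machinery is correct and calibrated under its own
assumptions — not that the pipeline's power on real tumor cohorts matches
these numbers.

## Numerical choices

- Binomial and hypergeometric tails are evaluated through survival
  functions (`pbinom`, `phyper`), not term summation; tests pin both to
  brute-force oracles at $10^{-12}$ on small grids.
- All empirical p-values use add-one smoothing with ties counted as
  exceedances, so no permutation p is ever 0 and FDR correction is safe.
- Every stochastic stage takes an explicit integer seed; identical seed
  and inputs give identical outputs (tested end to end). The pipeline
  derives fixed per-stage offsets from one master seed.
- Degenerate inputs: all-diploid genes score 0; an empty dual-significant
  set yields an empty risk set with a warning, not an error; an empty
  stratum is skipped with a warning; seeds absent from the PPI network and
  mutated genes absent from the annotation are dropped with logged counts.
- Integer copy numbers are required at ingest, which makes the two stated
  deletion thresholds ("= 0" and "< 1") coincide.

## Problem sizes

The test suite and the acceptance script run the demo cohort
(500 × 100, two strata), null cohorts of 200 genes × 60 samples, 1000
copy-number permutations, 10,000 multinomial cohorts, and 10,000–100,000
drug permutations; the full suite completes in about a minute and the
acceptance script in under a minute on one CPU.

## Limitations

Real cohort-scale claims (counts of risk genes, neighbors, significant
medications in actual TCGA/STRING/DrugBank/PubMed data) depend on those
resources and are out of scope here; the package verifies the method, the
calibration and the plumbing. The lexicon extractor is a deterministic
stand-in for semantic literature mining: it has perfect precision and
recall on planted whole-token mentions by construction and no ability to
judge relational context. The score-cutoff rules are data-driven
heuristics; for small significant sets the choice of
`cutoff_scope`/`cutoff_method` matters and both are exposed and recorded
in every risk-gene artifact.
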