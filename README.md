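# repurposeR

Genomic alteration-based drug repurposing for stratified tumor cohorts.

Developing new oncology drugs is slow and expensive; repositioning
medications with established safety profiles onto the genes that actually
drive a tumor subtype is a cheap, fast alternative. `repurposeR` implements
that idea as a tested, reusable pipeline for gene-level tumor genomics
(the motivating setting is head and neck cancer stratified by HPV status,
where drivers differ sharply between subtypes). It is aimed at
computational biologists who have per-sample copy-number and somatic
mutation tables and want a reproducible path from those tables to a
ranked, statistically gated list of candidate drugs.

## The method

Per stratum, and separately for amplifications, deletions and mutations:

- **High-level event calling.** Amplification: copy number > 4; deletion:
  copy number = 0 (diploid baseline 2).
- **Dual significance testing.** Each gene's event count *x* among *n*
  samples is tested two ways, and must pass both at FDR q < 0.05
  (Benjamini–Hochberg):
  - binomial upper tail
    P(X ≥ x) = Σₖ₌ₓⁿ C(n,k) p₀ᵏ (1−p₀)ⁿ⁻ᵏ, with p₀ the genome-wide
    background event rate of the stratum (for mutations: trials = all
    cohort mutations N, success probability p_g = L_g / Σ L_j over CDS
    lengths);
  - an add-one empirical permutation p-value
    (1 + #{count ≥ x}) / (N_perm + 1) against a pooled-resampling null
    (1000 permutations for copy number; 10,000 multinomial cohorts for
    mutations).
- **Composite scoring.** GISTIC-like score = mean log₂-adjusted amplitude
  (capped at CN 7) × percent frequency of high-level events; MutationScore
  = mutations-per-bp × percent of patients mutated. A data-driven cutoff
  (95th percentile or knee of the score curve) keeps the upper tail.
- **PPI expansion.** Risk genes gain their immediate STRING-style
  neighbors at combined score ≥ 700, with neighbor→seed provenance.
- **Literature validation.** Risk genes and neighbors are kept only with
  evidence support extracted from a cleaned abstract corpus (post-2000,
  deduplicated; whole-token lexicon extractor, pluggable backend).
- **Drug enrichment.** Each drug's target set is tested against the
  validated risk set by a right-tailed hypergeometric test over the
  druggable-gene universe and by 100,000 resampled gene sets; drugs
  passing both BH gates are retained and classified direct / indirect /
  both.

A synthetic-data module generates all six input kinds (copy-number table,
MAF, CDS lengths, HPV labels, PPI edges, drug–gene table, abstracts) with
planted signal and known ground truth, so the entire pipeline runs and is
verified with no downloads.

## Worked example

```r
library(repurposeR)

cfg    <- sim_config(seed = 1)            # 500 genes x 100 samples demo cohort
inputs <- simulate_cohort(cfg)            # all six inputs + ground truth
result <- run_full(inputs, pipeline_params(drug_permutations = 20000, seed = 1))
print(result)
#> Pipeline result over 2 stratum/strata
#>   hpv_positive: 20 risk genes (10 amp / 5 del / 5 som), 40 neighbors, 60 validated, 2 significant drugs
#>   hpv_negative: 20 risk genes (10 amp / 5 del / 5 som), 40 neighbors, 60 validated, 2 significant drugs

head(result$strata$hpv_positive$enrichment$results[,
  c("drug_id", "drug_name", "K", "x", "q_hypergeom", "q_empirical",
    "retained", "classification")], 4)
#>            drug_id    drug_name K x q_hypergeom q_empirical retained classification
#> 1   DRUG_TP_DIRECT Plantedtinib 5 5 0.001260466 0.005049748     TRUE         direct
#> 2 DRUG_TP_INDIRECT   Plantedmab 5 5 0.001260466 0.005049748     TRUE       indirect
#> 3          DB00159 Decoyvir-159 7 4 0.227248999 0.222188891    FALSE
#> 4          DB00006 Decoyvir-006 6 3 0.768467858 0.795840208    FALSE
```

The cohort was simulated with 10 amplified, 5 deleted and 5 driver genes
planted, plus two true-positive drugs among 200 decoys. The run recovers
all 20 planted risk genes in each stratum with zero false positives, and
both planted drugs — the one targeting risk genes directly and the one
targeting their PPI neighbors — rank first and second with dual q-values
far below 0.05, while no decoy passes the gate. `report_summary(result)`
yields the per-source cohort summary table and the
drug → target → risk-gene Sankey edge list; `write_*` helpers persist
every stage artifact as plain text.

Real data enter through the same door: `read_cnv_table()` /
`read_cnv_gdc()`, `read_maf()`, `read_gene_lengths()` or
`cds_lengths_from_gtf()`, `read_hpv_labels()`, `read_ppi_links()`,
`read_drug_interactions()`, `read_abstracts()` and `read_lexicon()`
produce exactly the structures `run_full()` consumes.

See `vignettes/methods.Rmd` for the statistical model, parameter
rationale, and the generator's scope.

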