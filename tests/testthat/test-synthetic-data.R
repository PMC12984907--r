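test_that("copy-number generator plants exact carriers and is deterministic", {
  cfg <- sim_config(seed = 21,
                    amp_spec = data.frame(gene_index = 7, level = 6,
                                          carrier_fraction = 0.3),
                    del_spec = NULL, driver_spec = NULL)
  sim <- simulate_cnv_cohort(cfg)
  g7 <- sim$cnv[sim$cnv$gene == "G0007", ]
  expect_equal(sum(g7$copy_number == 6), 30L)  # exactly 30% of 100 samples
  # determinism: same config, byte-identical table
  expect_identical(sim$cnv, simulate_cnv_cohort(cfg)$cnv)
  # pure null config produces only background draws in 0..7
  null_sim <- simulate_cnv_cohort(null_config(1))
  expect_true(all(null_sim$cnv$copy_number %in% 0:7))
  expect_length(null_sim$truth$amplified, 0)
  # carrier fraction rounding to zero samples is rejected
  tiny <- sim_config(seed = 1, n_samples = 10,
                     amp_spec = data.frame(gene_index = 1, level = 6,
                                           carrier_fraction = 0.01))
  expect_error(simulate_cnv_cohort(tiny), "carrier")
})

test_that("mutation generator conserves totals and boosts drivers", {
  cfg <- sim_config(seed = 22)
  sim <- simulate_maf(cfg)
  expect_equal(nrow(sim$maf), cfg$n_total_mutations)
  expect_identical(sim$maf, simulate_maf(cfg)$maf)
  expect_true(all(sim$gene_lengths$cds_length >= cfg$gene_length_range[1] &
                    sim$gene_lengths$cds_length <= cfg$gene_length_range[2]))
  # drivers accumulate well above their length-expected share
  counts <- table(sim$maf$gene)
  L <- sim$gene_lengths
  expected <- cfg$n_total_mutations * L$cds_length / sum(L$cds_length)
  names(expected) <- L$gene
  drv <- sim$truth$drivers
  expect_true(all(counts[drv] > 3 * expected[drv]))
  # no Silent rows when the synonymous fraction is zero
  cfg0 <- sim_config(seed = 22, synonymous_fraction = 0)
  expect_false(any(simulate_maf(cfg0)$maf$variant_classification == "Silent"))
})

test_that("PPI generator keeps background below the cutoff and plants above", {
  cfg <- sim_config(seed = 23)
  ppi <- simulate_ppi(cfg)
  planted <- ppi$truth$planted_edges
  bg <- ppi$edges[!ppi$edges$gene_b %in% ppi$truth$neighbors, ]
  expect_true(all(bg$combined_score < 700))
  expect_true(all(planted$combined_score >= 700))
  expect_equal(nrow(planted), 20 * cfg$neighbors_per_seed)
  expect_identical(ppi$edges, simulate_ppi(cfg)$edges)
})

test_that("drug generator plants exact target sets within size bounds", {
  cfg <- sim_config(seed = 24)
  ppi <- simulate_ppi(cfg)
  drugs <- simulate_drug_table(cfg, neighbors = ppi$truth$neighbors)
  ia <- drugs$interactions
  expect_setequal(ia$gene[ia$drug_id == "DRUG_TP_DIRECT"],
                  drugs$truth$DRUG_TP_DIRECT)
  expect_setequal(ia$gene[ia$drug_id == "DRUG_TP_INDIRECT"],
                  drugs$truth$DRUG_TP_INDIRECT)
  decoy_sizes <- table(ia$drug_id[grepl("^DB", ia$drug_id)])
  expect_true(all(decoy_sizes >= cfg$targets_per_drug_range[1] &
                    decoy_sizes <= cfg$targets_per_drug_range[2]))
  expect_identical(ia, simulate_drug_table(cfg, ppi$truth$neighbors)$interactions)
})

test_that("abstract generator plants mentions and dirty records for cleaning", {
  cfg <- sim_config(seed = 25)
  lit <- simulate_abstracts(cfg)
  # planted mention counts match the configuration
  expect_true(all(lit$truth == cfg$mentions_per_gene))
  # the corpus contains pre-2001, empty-abstract, and duplicate-pmid records
  expect_true(any(suppressWarnings(as.integer(lit$abstracts$year)) < 2001))
  expect_true(any(trimws(lit$abstracts$abstract) == ""))
  expect_true(anyDuplicated(lit$abstracts$pmid) > 0)
  expect_identical(lit$abstracts, simulate_abstracts(cfg)$abstracts)
})

test_that("the full bundle is internally consistent", {
  cfg <- sim_config(seed = 26)
  inp <- simulate_cohort(cfg)
  expect_setequal(unique(inp$cnv$sample_id), inp$labels$sample_id)
  expect_true(all(inp$maf$sample_id %in% inp$labels$sample_id))
  expect_true(all(unlist(inp$truth$genes) %in% inp$gene_lengths$gene))
  expect_true(all(inp$truth$neighbors %in% inp$lexicon))
  expect_true(all(unlist(inp$truth$drugs) %in% inp$drug_interactions$gene))
})
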