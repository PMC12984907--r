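maf_fixture <- function(genes, patients, classes = "Missense_Mutation") {
  data.frame(sample_id = patients, gene = genes,
             variant_classification = classes, stringsAsFactors = FALSE)
}

test_that("non-synonymous filtering keeps the allowlist and reports total N", {
  maf <- maf_fixture(c("A", "B"), c("P1", "P2"),
                     c("Missense_Mutation", "Silent"))
  flt <- filter_nonsynonymous(maf)
  expect_equal(nrow(flt$records), 1L)
  expect_equal(flt$n_total, 2L)

  flt <- filter_nonsynonymous(maf_fixture(character(0), character(0),
                                          character(0)))
  expect_equal(flt$n_total, 0L)

  maf <- maf_fixture(rep("A", 6), sprintf("P%d", 1:6),
                     c(rep("Missense_Mutation", 3), rep("Silent", 2),
                       "Frame_Shift_Del"))
  flt <- filter_nonsynonymous(maf)
  expect_equal(nrow(flt$records), 4L)
  expect_equal(flt$n_total, 6L)

  expect_warning(filter_nonsynonymous(
    maf_fixture("A", "P1", "Made_Up_Class")), "unknown")
})

test_that("TCGA barcodes reduce to 12-character patient ids", {
  expect_equal(patient_from_barcode("TCGA-AB-1234-01A-11D-A123-01"),
               "TCGA-AB-1234")
  expect_equal(patient_from_barcode("S007"), "S007")
})

test_that("per-gene stats count events, unique patients, and normalize", {
  lengths <- data.frame(gene = c("A", "B"), cds_length = c(1000L, 3000L))
  maf <- maf_fixture(rep("A", 5), c("P1", "P1", "P2", "P3", "P4"))
  st <- gene_mutation_stats(maf, lengths, cohort_size = 100)
  expect_equal(st$mutation_count, 5L)
  expect_equal(st$patient_count, 4L)
  expect_equal(st$normalized_count, 0.005)
  expect_equal(st$frequency_pct, 4)
  expect_equal(unname(mutation_score(st)), 0.02)

  # two events in one patient: one patient, two mutations
  st <- gene_mutation_stats(maf_fixture(c("A", "A"), c("P1", "P1")),
                            lengths, 10)
  expect_equal(st$patient_count, 1L)
  expect_equal(st$mutation_count, 2L)

  # unmutated genes are absent; unannotated genes skipped with warning
  expect_false("B" %in% st$gene)
  expect_warning(
    st2 <- gene_mutation_stats(maf_fixture(c("A", "ZZZ"), c("P1", "P2")),
                               lengths, 10),
    "absent")
  expect_setequal(attr(st2, "skipped_genes"), "ZZZ")

  # halving the CDS length doubles the mutation score
  half <- lengths
  half$cds_length[1] <- 500L
  s1 <- mutation_score(gene_mutation_stats(maf, lengths, 100))
  s2 <- mutation_score(gene_mutation_stats(maf, half, 100))
  expect_equal(unname(s2), 2 * unname(s1))

  expect_error(gene_mutation_stats(maf, lengths, 0), "positive")
})

test_that("length-probability binomial test matches the summation oracle", {
  lengths <- data.frame(gene = c("A", "B"), cds_length = c(1000L, 3000L))
  st <- gene_mutation_stats(
    maf_fixture(rep("A", 4), sprintf("P%d", 1:4)), lengths, 10)
  p <- som_binomial_test(st, n_total = 8, gene_lengths = lengths)
  expect_equal(unname(p["A"]), oracle_binom_tail(4, 8, 0.25),
               tolerance = 1e-12)

  # same x and N: the longer gene gets the larger p-value
  st2 <- rbind(st, st)
  st2$gene <- c("A", "B")
  p2 <- som_binomial_test(st2, 8, lengths)
  expect_gt(p2["B"], p2["A"])
})

test_that("multinomial null conserves totals and is deterministic", {
  lengths <- data.frame(gene = sprintf("g%d", 1:40),
                        cds_length = sample(500:5000, 40))
  # conservation checked on raw draws
  set.seed(1)
  draws <- stats::rmultinom(200, 300, lengths$cds_length / sum(lengths$cds_length))
  expect_true(all(colSums(draws) == 300))

  st <- data.frame(gene = c("g1", "g5"), mutation_count = c(6L, 1L))
  p1 <- som_multinomial_permutation(st, 300, lengths, 500, seed = 5)
  p2 <- som_multinomial_permutation(st, 300, lengths, 500, seed = 5)
  expect_identical(p1, p2)

  # degenerate single-gene universe: every draw equals N_total
  uni1 <- data.frame(gene = "only", cds_length = 1000L)
  st1 <- data.frame(gene = "only", mutation_count = 50L)
  expect_equal(unname(som_multinomial_permutation(st1, 50, uni1, 100,
                                                  seed = 1)["only"]), 1.0)

  # binomial marginal sampler agrees with the joint multinomial within MC error
  pm <- som_multinomial_permutation(st, 300, lengths, 4000, seed = 7,
                                    method = "multinomial")
  pb <- som_multinomial_permutation(st, 300, lengths, 4000, seed = 7,
                                    method = "binomial")
  se <- 3 * sqrt(pm * (1 - pm) / 4000) + 2 / 4001
  expect_true(all(abs(pm - pb) <= se))
})

test_that("full mutation analysis recovers implanted drivers", {
  # 300-gene universe, ~2000 mutations, 5 drivers at 10x length-expected rate
  cfg <- sim_config(seed = 17, n_genes = 300, n_samples = 100,
                    hpv_positive_fraction = 1,
                    driver_spec = data.frame(gene_index = 21:25,
                                             multiplier = 10,
                                             min_patient_fraction = 0.1),
                    n_total_mutations = 2000)
  sim <- simulate_maf(cfg)
  res <- analyze_som(sim$maf, sim$gene_lengths, cohort_size = 100, seed = 17)
  expect_setequal(intersect(res$risk$genes, sim$truth$drivers),
                  sim$truth$drivers)
  expect_lte(length(setdiff(res$risk$genes, sim$truth$drivers)), 1)
})
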