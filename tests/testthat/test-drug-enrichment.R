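interactions_fixture <- function(targets) {
  do.call(rbind, lapply(names(targets), function(d) {
    data.frame(drug_id = d, drug_name = toupper(d), gene = targets[[d]],
               action = "inhibitor", stringsAsFactors = FALSE)
  }))
}

test_that("universe construction deduplicates drugs and genes", {
  ia <- interactions_fixture(list(d1 = c("A", "B"), d2 = c("C", "A"),
                                  d3 = c("A", "A")))
  uni <- build_universe(ia)
  expect_setequal(uni$universe, c("A", "B", "C"))
  expect_equal(length(uni$targets$d3), 1L)  # duplicate rows counted once
  expect_error(build_universe(ia[0, ]), "non-empty")
})

test_that("hypergeometric enrichment matches enumeration on the toy universe", {
  universe <- sprintf("u%02d", 1:10)
  targets <- universe[1:3]
  risk <- universe[c(1, 2, 4, 5)]   # overlap 2 with targets
  expect_equal(drug_hypergeom_test(targets, risk, universe), 1 / 3,
               tolerance = 1e-12)
  expect_equal(drug_hypergeom_test(targets, universe[5:8], universe), 1.0)
  # drug targeting the whole universe: overlap is certain
  expect_equal(drug_hypergeom_test(universe, risk, universe), 1.0)
  expect_error(drug_hypergeom_test(targets, risk, character(0)), "empty")
})

test_that("permutation enrichment converges to the hypergeometric value", {
  universe <- sprintf("u%02d", 1:10)
  targets <- universe[1:3]
  risk <- universe[c(1, 2, 4, 5)]
  p_hyper <- 1 / 3
  p_perm <- drug_permutation_test(targets, risk, universe,
                                  n_permutations = 100000, seed = 2)
  se <- 3 * sqrt(p_hyper * (1 - p_hyper) / 100000) + 1 / 100001
  expect_lt(abs(p_perm - p_hyper), se)
  # determinism and bounds
  expect_identical(p_perm, drug_permutation_test(targets, risk, universe,
                                                 100000, seed = 2))
  expect_gte(p_perm, 1 / 100001)
  expect_lte(p_perm, 1)
  # zero overlap: p = 1 in both tests
  expect_equal(drug_permutation_test(universe[9], universe[1:2], universe,
                                     500, seed = 1), 1)
})

test_that("enrichment retains the planted drug and classifies overlap", {
  set.seed(8)
  genes <- sprintf("g%03d", 1:500)
  risk_direct <- genes[1:6]
  risk_nb <- genes[7:10]
  decoys <- stats::setNames(
    lapply(1:60, function(i) sample(genes, 5)), sprintf("d%02d", 1:60))
  planted <- list(hit = c(risk_direct[1:3], risk_nb[1:2]))
  ia <- interactions_fixture(c(decoys, planted))
  res <- enrich_all(ia, risk_direct, risk_nb, n_permutations = 20000,
                    seed = 8)
  tab <- res$results
  expect_true(tab$retained[tab$drug_id == "hit"])
  expect_equal(tab$classification[tab$drug_id == "hit"], "both")
  expect_equal(tab$drug_id[1], "hit")  # ranked first
  # drugs with zero overlap are reported but never retained
  expect_true(all(!tab$retained[tab$x == 0]))
  # x never exceeds min(K, n)
  expect_true(all(tab$x <= pmin(tab$K, res$n_risk)))

  # empty risk set: empty result with warning
  expect_warning(res0 <- enrich_all(ia, character(0)), "empty")
  expect_equal(nrow(res0$results), 0L)
})

test_that("dual gating keeps decisions stable between 10k and 100k permutations", {
  set.seed(12)
  genes <- sprintf("g%03d", 1:300)
  risk <- genes[1:10]
  decoys <- stats::setNames(
    lapply(1:40, function(i) sample(genes, 5)), sprintf("d%02d", 1:40))
  ia <- interactions_fixture(c(decoys, list(hit = risk[1:5])))
  r1 <- enrich_all(ia, risk, n_permutations = 10000, seed = 3)$results
  r2 <- enrich_all(ia, risk, n_permutations = 100000, seed = 3)$results
  r2 <- r2[match(r1$drug_id, r2$drug_id), ]
  expect_equal(r1$retained, r2$retained)
})
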