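# small long-format helper: one gene, given per-sample copy numbers
cnv_fixture <- function(values, gene = "G1") {
  data.frame(sample_id = sprintf("S%02d", seq_along(values)), gene = gene,
             copy_number = as.integer(values), stringsAsFactors = FALSE)
}

test_that("event calling applies the high-level thresholds and amplitude rules", {
  st <- call_cnv_events(cnv_fixture(c(5, 2, 2)), "amplification")
  expect_equal(st$high_event_count, 1L)          # CNV = 5 > 4 is high-level
  st <- call_cnv_events(cnv_fixture(c(2, 2)), "amplification")
  expect_equal(st$high_event_count, 0L)          # diploid baseline
  expect_equal(st$amplitude_sum, 0)
  st <- call_cnv_events(cnv_fixture(c(2, 2)), "deletion")
  expect_equal(st$high_event_count, 0L)

  # cap at CNV = 7: amplitude of CNV = 9 is log2(7) - 1
  st <- call_cnv_events(cnv_fixture(c(9, 2)), "amplification")
  expect_equal(st$amplitude_sum, log2(7) - 1, tolerance = 1e-12)

  # deletion intensities: +1 at CNV = 1, +2 at CNV = 0
  st <- call_cnv_events(cnv_fixture(c(0, 1, 2)), "deletion")
  expect_equal(st$amplitude_sum, 3)
  expect_equal(st$high_event_count, 1L)          # only CNV = 0 is high-level
  expect_equal(st$altered_sample_count, 2L)

  # alternative log rule also zeroes at the diploid baseline
  expect_equal(cnv_amplitude(2L, "amplification", "log2_shifted"), 0)
  expect_equal(cnv_amplitude(3L, "amplification", "log2_shifted"), 1)

  expect_error(call_cnv_events(cnv_fixture(c(-1, 2)), "amplification"),
               "non-negative")
  expect_error(call_cnv_events(cnv_fixture(2), "sideways"))
})

test_that("background rate is the pooled exceedance fraction", {
  pool <- c(2, 2, 5, 7, 2, 0, 2, 2, 1, 2)
  expect_equal(background_rate(pool, "amplification"), 0.2)
  expect_equal(background_rate(pool, "deletion"), 0.1)
  expect_equal(background_rate(rep(2, 50), "amplification"), 0)
  expect_error(background_rate(integer(0), "deletion"), "empty")
})

test_that("binomial test reproduces the shared tail and is monotone", {
  st <- data.frame(gene = c("A", "B", "C"), n_samples = 10L,
                   high_event_count = c(0L, 2L, 4L))
  p <- cnv_binomial_test(st, 0.1)
  expect_equal(unname(p["A"]), 1.0)
  expect_equal(unname(p["B"]), oracle_binom_tail(2, 10, 0.1),
               tolerance = 1e-12)
  expect_true(p["C"] <= p["B"])  # more events, same n: smaller p
})

test_that("GISTIC-like scores match hand-derived fixtures", {
  # 10 samples, two CNV=6 amplifications: mean amplitude log2(6)-1, 20% freq
  st <- call_cnv_events(cnv_fixture(c(6, 6, rep(2, 8))), "amplification")
  expect_equal(unname(gistic_like_score(st)), (log2(6) - 1) * 20,
               tolerance = 1e-10)
  # 10 samples, one CNV=0 and one CNV=1: mean intensity 1.5, 10% CNV=0 freq
  st <- call_cnv_events(cnv_fixture(c(0, 1, rep(2, 8))), "deletion")
  expect_equal(unname(gistic_like_score(st)), 15.0)
  # all-diploid gene scores zero in both directions
  for (d in c("amplification", "deletion")) {
    st <- call_cnv_events(cnv_fixture(rep(2, 10)), d)
    expect_equal(unname(gistic_like_score(st)), 0)
  }
  # replacing one diploid sample by a high-level event strictly raises it
  lo <- call_cnv_events(cnv_fixture(c(6, rep(2, 9))), "amplification")
  hi <- call_cnv_events(cnv_fixture(c(6, 6, rep(2, 8))), "amplification")
  expect_gt(gistic_like_score(hi), gistic_like_score(lo))
})

test_that("permutation null is deterministic under seed and reused across genes", {
  pool <- c(rep(2L, 90), rep(6L, 6), rep(0L, 4))
  n1 <- cnv_permutation_null(pool, 20, "amplification", 200, seed = 11)
  n2 <- cnv_permutation_null(pool, 20, "amplification", 200, seed = 11)
  expect_identical(n1, n2)
  expect_false(identical(
    n1, cnv_permutation_null(pool, 20, "amplification", 200, seed = 12)))

  st <- data.frame(gene = c("A", "B"), n_samples = 20L,
                   high_event_count = c(0L, 8L))
  p <- cnv_permutation_test(st, pool, 20, "amplification", 200, seed = 11)
  expect_equal(unname(p["A"]), 1.0)
  # reuse guard: the per-gene p equals empirical_p against the shared null
  expect_equal(unname(p["B"]), empirical_p(8, n1))
  expect_error(cnv_permutation_null(pool, 20, "amplification", 0), ">= 1")
})

test_that("risk-gene selection applies the dual gate and score cutoffs", {
  base <- data.frame(gene = sprintf("g%03d", 1:100), score = as.numeric(1:100),
                     q_binomial = 0.01, q_empirical = 0.01,
                     stringsAsFactors = FALSE)
  # dual-significant scores 1..100 at the 95th percentile: top 5 retained
  sel <- select_risk_genes(base, cutoff_scope = "significant")
  expect_setequal(sel$genes, sprintf("g%03d", 96:100))

  # a gene failing either q-gate is excluded no matter its score
  mix <- base
  mix$q_empirical[100] <- 0.2
  sel <- select_risk_genes(mix, cutoff_scope = "significant")
  expect_false("g100" %in% sel$genes)

  # a single dual-significant gene is retained regardless of cutoff method
  one <- base
  one$q_binomial[-37] <- 0.9
  for (m in c("percentile", "knee")) {
    sel <- select_risk_genes(one, cutoff_method = m)
    expect_equal(sel$genes, "g037")
  }

  # no dual-significant genes: empty set with a warning, not an error
  none <- base
  none$q_binomial <- 0.9
  expect_warning(sel <- select_risk_genes(none), "dual")
  expect_length(sel$genes, 0)

  # knee cutoff separates a planted high cluster from background
  knee <- data.frame(gene = sprintf("k%02d", 1:50),
                     score = c(rep(30, 5) + (1:5) / 10, runif(45, 0, 2)),
                     q_binomial = c(rep(0.001, 5), rep(0.9, 45)),
                     q_empirical = c(rep(0.001, 5), rep(0.9, 45)))
  sel <- select_risk_genes(knee, cutoff_method = "knee", cutoff_scope = "all")
  expect_setequal(sel$genes, sprintf("k%02d", 1:5))
})

test_that("full CNV analysis recovers implanted amplifications", {
  cfg <- sim_config(seed = 31, hpv_positive_fraction = 1)
  sim <- simulate_cnv_cohort(cfg)
  res <- analyze_cnv(sim$cnv, "amplification", seed = 31)
  expect_setequal(intersect(res$risk$genes, sim$truth$amplified),
                  sim$truth$amplified)
  expect_lte(length(setdiff(res$risk$genes, sim$truth$amplified)), 2)
  # untested (zero-event) genes carry NA q-values but are still reported
  expect_true(all(is.na(res$stats$q_binomial[res$stats$high_event_count == 0])))
  expect_equal(nrow(res$stats), cfg$n_genes)
})
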