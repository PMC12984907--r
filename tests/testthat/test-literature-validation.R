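abstracts_fixture <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(pmid = r[[1]], title = r[[2]], year = r[[3]], abstract = r[[4]],
               stringsAsFactors = FALSE)
  }))
}

test_that("cleaning drops missing abstracts, old years, and duplicate pmids", {
  corpus <- abstracts_fixture(
    list("p1", "ok", 2010, "EGFR matters."),
    list("p2", "old", 1999, "TP53 matters."),
    list("p3", "empty", 2015, ""),
    list("p4", "badyear", "n.d.", "Something."),
    list("p1", "dup", 2012, "EGFR again."))
  out <- clean_abstracts(corpus)
  expect_equal(out$pmid, "p1")
  expect_equal(out$title, "ok")
  dc <- attr(out, "drop_counts")
  expect_equal(unname(dc["missing_abstract"]), 1L)
  expect_equal(unname(dc["old_year"]), 1L)
  expect_equal(unname(dc["bad_year"]), 1L)
  expect_equal(unname(dc["duplicate_pmid"]), 1L)
  # boundary: 2001 is retained under the default filter, 2000 is not
  edge <- abstracts_fixture(list("a", "t", 2001, "x."), list("b", "t", 2000, "y."))
  expect_equal(clean_abstracts(edge)$pmid, "a")
  # idempotence on already-clean input
  expect_equal(clean_abstracts(out)$pmid, out$pmid)
})

test_that("lexicon extraction matches whole tokens inside sentences", {
  corpus <- abstracts_fixture(
    list("p1", "t", 2010,
         "EGFR overexpression drives HNC. Cisplatin resistance was noted."),
    list("p2", "t", 2011, "Nothing relevant here."),
    list("p3", "t", 2012, "VEGFR is different."))
  ex <- lexicon_extractor(c("EGFR", "TP53"))
  ev <- extract_targets(corpus, ex)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$gene, "EGFR")
  expect_equal(ev$evidence_sentence, "EGFR overexpression drives HNC.")
  # sentence round-trip: the evidence is a verbatim substring of its abstract
  expect_true(grepl(ev$evidence_sentence, corpus$abstract[1], fixed = TRUE))

  # drug co-mentions are annotated from the same sentence
  ex2 <- lexicon_extractor(c("EGFR"), drug_lexicon = c("Cisplatin"))
  ev2 <- extract_targets(corpus, ex2)
  expect_equal(ev2$drugs, "")  # Cisplatin sits in a different sentence
  corpus2 <- abstracts_fixture(
    list("p9", "t", 2010, "Cisplatin inhibits EGFR in tumors."))
  expect_equal(extract_targets(corpus2, ex2)$drugs, "Cisplatin")
})

test_that("invalid backend output is rejected and failures abort past 50%", {
  corpus <- abstracts_fixture(list("p1", "t", 2010, "EGFR drives disease."))
  bad_backend <- function(record) {
    data.frame(gene = "EGFR", sentence = "Not from the abstract.", drugs = "")
  }
  ev <- extract_targets(corpus, bad_backend)
  expect_equal(nrow(ev), 0L)
  expect_equal(unname(attr(ev, "rejected")["invalid_records"]), 1L)

  failing <- function(record) stop("backend down")
  expect_error(extract_targets(corpus, failing), "half")
})

test_that("validation thresholds candidates by distinct supporting articles", {
  ev <- data.frame(
    pmid = c("p1", "p2", "p3", "p3"),
    gene = c("PIK3CA", "PIK3CA", "PIK3CA", "SOX2"),
    evidence_sentence = "s", drugs = "", stringsAsFactors = FALSE)
  v <- validate_genes(c("PIK3CA", "NOVEL1"), ev)
  expect_equal(v$genes, "PIK3CA")
  expect_length(v$support$PIK3CA, 3)
  expect_length(validate_genes("X", ev[0, ])$genes, 0)
  # min_articles boundary: one supporting pmid is not enough at 2
  v2 <- validate_genes(c("SOX2"), ev, min_articles = 2)
  expect_length(v2$genes, 0)
})

test_that("planted mentions are recovered with perfect recall and precision", {
  cfg <- sim_config(seed = 3)
  lit <- simulate_abstracts(cfg)
  planted <- names(lit$truth)
  corpus <- clean_abstracts(lit$abstracts)
  lex <- sim_config(seed = 3) |> (\(c) sprintf("G%04d", 1:c$n_genes))()
  ev <- extract_targets(corpus, lexicon_extractor(lex))
  # recall: every planted gene validated with its planted support count
  v <- validate_genes(planted, ev)
  expect_setequal(v$genes, planted)
  for (g in planted) {
    expect_length(v$support[[g]], unname(lit$truth[g]))
  }
  # precision: no unplanted gene is ever extracted
  expect_length(setdiff(unique(ev$gene), planted), 0)
})
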