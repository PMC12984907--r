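#' @title End-to-end pipeline orchestration
#' @name pipeline
#' @description
#' Runs the full workflow per HPV stratum: copy-number amplification and
#' deletion analysis, somatic-mutation analysis, union of the three
#' risk-gene sources, PPI neighbor expansion, literature validation of risk
#' genes and neighbors, and drug enrichment on the validated sets, with
#' per-source summary counts and a Sankey-style drug/target/risk-gene edge
#' table. All stage functions are exported individually, so any stage can be
#' re-run in isolation on saved intermediate tables.
NULL

#' Partition samples into HPV strata
#'
#' @param labels data.frame with columns `sample_id`, `hpv_status`
#'   (`"positive"` / `"negative"`; other values are dropped with a message).
#' @return named list of sample-id character vectors
#'   (`hpv_positive`, `hpv_negative`).
#' @export
stratify_samples <- function(labels) {
  need <- c("sample_id", "hpv_status")
  if (!is.data.frame(labels) || !all(need %in% names(labels))) {
    stop("`labels` must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  status <- tolower(as.character(labels$hpv_status))
  bad <- !status %in% c("positive", "negative")
  if (any(bad)) {
    message(sum(bad), " sample(s) with unrecognised HPV status dropped")
  }
  list(hpv_positive = unique(labels$sample_id[status == "positive"]),
       hpv_negative = unique(labels$sample_id[status == "negative"]))
}

#' Default pipeline parameters
#'
#' Every threshold the method uses, as one explicit list: the dual-gate
#' alpha, the permutation/simulation counts per stage (1000 pooled CNV
#' permutations, 10000 multinomial mutation cohorts, 100000 drug-set
#' resamples), the PPI combined-score cutoff (700), the literature year
#' filter (2001, i.e. after 2000) and support threshold, and the score
#' cutoff rule (95th percentile of all tested genes' scores).
#'
#' @param ... overrides for any default element.
#' @return named list of parameters.
#' @export
pipeline_params <- function(...) {
  params <- list(alpha = 0.05, cnv_permutations = 1000,
                 som_simulations = 10000, drug_permutations = 100000,
                 ppi_min_score = 700, ppi_strict = FALSE,
                 min_year = 2001, min_articles = 1,
                 cutoff_method = "percentile", cutoff_param = 95,
                 cutoff_scope = "all", amplitude_scope = "altered",
                 log_rule = "log2_minus_1", seed = 1L)
  override <- list(...)
  unknown <- setdiff(names(override), names(params))
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  params[names(override)] <- override
  params
}

#' Run the full repurposing pipeline on in-memory inputs
#'
#' @param inputs named list with elements `cnv` (long copy-number table),
#'   `maf` (mutation records), `gene_lengths`, `labels`, `ppi_edges`,
#'   `drug_interactions`, `abstracts`, `lexicon` -- the formats produced by
#'   the `read_*` helpers or by [simulate_cohort()].
#' @param params parameter list from [pipeline_params()].
#' @return object of class `pipeline_result`: per-stratum results (each with
#'   `cnv_amplification`, `cnv_deletion`, `somatic_mutation` analysis
#'   objects, `risk_union`, `neighbors`, `validated_direct`,
#'   `validated_neighbors`, `enrichment`, `attrition`), plus the shared
#'   `evidence` table and the `params` used.
#' @export
run_full <- function(inputs, params = pipeline_params()) {
  need <- c("cnv", "maf", "gene_lengths", "labels", "ppi_edges",
            "drug_interactions", "abstracts", "lexicon")
  miss <- setdiff(need, names(inputs))
  if (length(miss)) {
    stop("missing input element(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  strata <- stratify_samples(inputs$labels)

  corpus <- clean_abstracts(inputs$abstracts, min_year = params$min_year)
  extractor <- lexicon_extractor(inputs$lexicon)
  evidence <- extract_targets(corpus, extractor)

  results <- list()
  for (stratum in names(strata)) {
    samples <- strata[[stratum]]
    if (length(samples) == 0L) {
      warning("stratum ", stratum, " is empty; skipped", call. = FALSE)
      next
    }
    cnv_s <- inputs$cnv[inputs$cnv$sample_id %in% samples, , drop = FALSE]
    maf_s <- inputs$maf[inputs$maf$sample_id %in% samples, , drop = FALSE]
    attrition <- c(
      stratum_samples = length(samples),
      cnv_samples = length(unique(cnv_s$sample_id)),
      maf_patients = length(unique(maf_s$sample_id)),
      cnv_rows_dropped = nrow(inputs$cnv[!inputs$cnv$sample_id %in%
                                           unlist(strata), , drop = FALSE]))

    amp <- analyze_cnv(cnv_s, "amplification", alpha = params$alpha,
                       n_permutations = params$cnv_permutations,
                       seed = params$seed + 11L,
                       cutoff_method = params$cutoff_method,
                       cutoff_param = params$cutoff_param,
                       cutoff_scope = params$cutoff_scope,
                       amplitude_scope = params$amplitude_scope,
                       log_rule = params$log_rule, stratum = stratum)
    del <- analyze_cnv(cnv_s, "deletion", alpha = params$alpha,
                       n_permutations = params$cnv_permutations,
                       seed = params$seed + 12L,
                       cutoff_method = params$cutoff_method,
                       cutoff_param = params$cutoff_param,
                       cutoff_scope = params$cutoff_scope,
                       amplitude_scope = params$amplitude_scope,
                       log_rule = params$log_rule, stratum = stratum)
    som <- analyze_som(maf_s, inputs$gene_lengths,
                       cohort_size = length(samples), alpha = params$alpha,
                       n_simulations = params$som_simulations,
                       seed = params$seed + 13L,
                       cutoff_method = params$cutoff_method,
                       cutoff_param = params$cutoff_param,
                       cutoff_scope = params$cutoff_scope, stratum = stratum)

    risk_sources <- list(cnv_amplification = amp$risk$genes,
                         cnv_deletion = del$risk$genes,
                         somatic_mutation = som$risk$genes)
    risk_union <- unique(unlist(risk_sources, use.names = FALSE))

    neighbors <- if (length(risk_union)) {
      expand_neighbors(risk_union, inputs$ppi_edges,
                       min_score = params$ppi_min_score,
                       strict = params$ppi_strict)
    } else NULL

    validated_direct <- validate_genes(risk_union, evidence,
                                       min_articles = params$min_articles)
    validated_neighbors <- validate_genes(
      if (is.null(neighbors)) character(0) else neighbor_genes(neighbors),
      evidence, min_articles = params$min_articles)

    enrichment <- enrich_all(inputs$drug_interactions,
                             risk_direct = validated_direct$genes,
                             risk_neighbors = validated_neighbors$genes,
                             alpha = params$alpha,
                             n_permutations = params$drug_permutations,
                             seed = params$seed + 14L)

    results[[stratum]] <- list(
      stratum = stratum, cnv_amplification = amp, cnv_deletion = del,
      somatic_mutation = som, risk_sources = risk_sources,
      risk_union = risk_union, neighbors = neighbors,
      validated_direct = validated_direct,
      validated_neighbors = validated_neighbors,
      enrichment = enrichment, attrition = attrition)
  }
  structure(list(strata = results, evidence = evidence, params = params),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result over", length(x$strata), "stratum/strata\n")
  for (s in x$strata) {
    n_drugs <- sum(s$enrichment$results$retained)
    cat(sprintf(
      "  %s: %d risk genes (%d amp / %d del / %d som), %d neighbors, %d validated, %d significant drugs\n",
      s$stratum, length(s$risk_union),
      length(s$risk_sources$cnv_amplification),
      length(s$risk_sources$cnv_deletion),
      length(s$risk_sources$somatic_mutation),
      if (is.null(s$neighbors)) 0L else length(s$neighbors$entries),
      length(s$validated_direct$genes) + length(s$validated_neighbors$genes),
      n_drugs))
  }
  invisible(x)
}

# neighbors of a specific source's risk genes, from the joint provenance map
source_neighbors <- function(neighbors, source_genes) {
  if (is.null(neighbors) || !length(source_genes)) return(character(0))
  hit <- vapply(neighbors$entries,
                function(seeds) any(seeds %in% source_genes), logical(1))
  names(neighbors$entries)[hit]
}

#' Per-source cohort summary and Sankey edge table
#'
#' The summary has one row per stratum and risk-gene source with the counts
#' of: high-risk genes, risk genes available as drug targets, immediate PPI
#' neighbors (of that source's genes, from the joint expansion), drug-
#' annotated genes (risk genes plus neighbors present in the drug
#' universe), and significant medications whose enrichment overlap touches
#' that source's genes or their neighbors. The Sankey table lists, for every
#' retained drug, `drug -> target gene -> seed risk gene` edges (a directly
#' targeted risk gene is its own seed).
#'
#' @param result a `pipeline_result` from [run_full()].
#' @return list with `summary` (data.frame) and `sankey` (data.frame:
#'   `stratum`, `drug_name`, `target_gene`, `risk_gene`, `link`).
#' @export
report_summary <- function(result) {
  stopifnot(inherits(result, "pipeline_result"))
  summary_rows <- list()
  sankey_rows <- list()
  for (s in result$strata) {
    universe <- s$enrichment$universe
    retained <- s$enrichment$results[s$enrichment$results$retained, ,
                                     drop = FALSE]
    for (src in names(s$risk_sources)) {
      genes <- s$risk_sources[[src]]
      nb <- source_neighbors(s$neighbors, genes)
      annotated <- intersect(union(genes, nb), universe)
      n_drugs <- if (nrow(retained)) {
        sum(vapply(seq_len(nrow(retained)), function(i) {
          ov <- strsplit(retained$overlapping_genes[i], ";", fixed = TRUE)[[1]]
          any(ov %in% genes) || any(ov %in% nb)
        }, logical(1)))
      } else 0L
      summary_rows[[length(summary_rows) + 1L]] <- data.frame(
        stratum = s$stratum, source = src,
        high_risk_genes = length(genes),
        risk_genes_drug_targets = length(intersect(genes, universe)),
        immediate_neighbors = length(nb),
        drug_annotated_genes = length(annotated),
        significant_medications = n_drugs,
        stringsAsFactors = FALSE)
    }
    if (nrow(retained) && !is.null(s$neighbors)) {
      et <- s$neighbors$edge_table
      for (i in seq_len(nrow(retained))) {
        ov <- strsplit(retained$overlapping_genes[i], ";", fixed = TRUE)[[1]]
        for (g in ov) {
          seeds <- if (g %in% s$risk_union) g else
            et$seed[et$neighbor == g]
          if (!length(seeds)) next
          sankey_rows[[length(sankey_rows) + 1L]] <- data.frame(
            stratum = s$stratum, drug_name = retained$drug_name[i],
            target_gene = g, risk_gene = seeds,
            link = ifelse(g %in% s$risk_union, "direct", "neighbor"),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  summary <- if (length(summary_rows)) do.call(rbind, summary_rows) else
    data.frame()
  sankey <- if (length(sankey_rows)) do.call(rbind, sankey_rows) else
    data.frame(stratum = character(0), drug_name = character(0),
               target_gene = character(0), risk_gene = character(0),
               link = character(0))
  rownames(summary) <- rownames(sankey) <- NULL
  list(summary = summary, sankey = sankey)
}
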