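#' @title Somatic mutation burden analysis
#' @name som_analysis
#' @description
#' Length-normalized gene-level mutation burden testing from MAF-style
#' records. Non-synonymous events per gene are tested against a
#' CDS-length-proportional binomial null (trials = all mutations in the
#' cohort, including synonymous ones, which set the unbiased background rate)
#' and against a multinomial permutation null that redistributes the cohort's
#' mutations over the annotation universe by length. Dual-significant genes
#' are ranked by a composite mutation score.
NULL

#' MAF variant classes counted as non-synonymous
#'
#' The standard protein-altering MAF `Variant_Classification` values: missense
#' and nonsense substitutions, frameshift and in-frame indels, splice-site,
#' translation-start and stop-loss changes.
#'
#' @return character vector of classification labels.
#' @export
nonsynonymous_classes <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Del",
    "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins", "Splice_Site",
    "Translation_Start_Site", "Nonstop_Mutation")
}

#' Filter mutation records to non-synonymous classes
#'
#' Retains protein-altering records and reports the total record count
#' including synonymous ones, which is the binomial trial size `N` for the
#' burden test. Classification labels outside both the allowlist and the
#' known synonymous/non-coding set are dropped with a warning (configurable
#' by extending `allowlist`).
#'
#' @param mutations data.frame with columns `sample_id`, `gene`,
#'   `variant_classification`.
#' @param allowlist classifications treated as non-synonymous
#'   (default [nonsynonymous_classes()]).
#' @return list with `records` (the retained data.frame) and `n_total`
#'   (total mutation count including synonymous).
#' @export
filter_nonsynonymous <- function(mutations, allowlist = nonsynonymous_classes()) {
  need <- c("sample_id", "gene", "variant_classification")
  if (!is.data.frame(mutations) || !all(need %in% names(mutations))) {
    stop("`mutations` must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  known_other <- c("Silent", "3'UTR", "5'UTR", "3'Flank", "5'Flank", "Intron",
                   "IGR", "RNA", "lincRNA", "De_novo_Start_InFrame",
                   "De_novo_Start_OutOfFrame", "Targeted_Region")
  cls <- mutations$variant_classification
  unknown <- setdiff(unique(cls), c(allowlist, known_other))
  if (length(unknown)) {
    warning("unknown variant classifications dropped: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  list(records = mutations[cls %in% allowlist, , drop = FALSE],
       n_total = nrow(mutations))
}

#' Patient identifiers from tumor sample barcodes
#'
#' TCGA-style barcodes (`TCGA-XX-XXXX-...`) are truncated to the standard
#' 12-character patient prefix; other identifiers pass through unchanged.
#'
#' @param barcodes character vector of sample barcodes.
#' @param pattern regular expression recognising truncatable barcodes.
#' @param nchar prefix length retained for matching barcodes.
#' @return character vector of patient identifiers.
#' @export
patient_from_barcode <- function(barcodes, pattern = "^TCGA-", nchar = 12L) {
  out <- as.character(barcodes)
  hit <- grepl(pattern, out)
  out[hit] <- substr(out[hit], 1L, nchar)
  out
}

#' Per-gene non-synonymous mutation statistics
#'
#' Counts non-synonymous events and unique mutated patients per gene, and
#' derives the length-normalized burden (mutations per bp of CDS) and the
#' cohort frequency in percent. Only mutated genes appear; genes absent from
#' the annotation are excluded from testing and listed in the
#' `skipped_genes` attribute.
#'
#' @param records non-synonymous mutation data.frame (`sample_id`, `gene`),
#'   e.g. `filter_nonsynonymous(...)$records`.
#' @param gene_lengths data.frame with columns `gene`, `cds_length`.
#' @param cohort_size number of patients in the stratum.
#' @return data.frame with columns `gene`, `mutation_count`, `patient_count`,
#'   `cds_length`, `normalized_count`, `frequency_pct`.
#' @export
gene_mutation_stats <- function(records, gene_lengths, cohort_size) {
  if (length(cohort_size) != 1L || cohort_size < 1) {
    stop("`cohort_size` must be a positive integer", call. = FALSE)
  }
  if (!all(c("gene", "cds_length") %in% names(gene_lengths)) ||
      anyDuplicated(gene_lengths$gene) ||
      any(gene_lengths$cds_length <= 0)) {
    stop("`gene_lengths` must have unique genes with positive cds_length",
         call. = FALSE)
  }
  if (nrow(records) == 0L) {
    out <- data.frame(gene = character(0), mutation_count = integer(0),
                      patient_count = integer(0), cds_length = integer(0),
                      normalized_count = numeric(0), frequency_pct = numeric(0))
    attr(out, "skipped_genes") <- character(0)
    return(out)
  }
  skipped <- setdiff(unique(records$gene), gene_lengths$gene)
  if (length(skipped)) {
    warning(length(skipped), " mutated gene(s) absent from the annotation ",
            "were excluded from testing", call. = FALSE)
    records <- records[records$gene %in% gene_lengths$gene, , drop = FALSE]
  }
  gene <- factor(records$gene, levels = unique(records$gene))
  out <- data.frame(
    gene = levels(gene),
    mutation_count = as.integer(table(gene)),
    patient_count = as.integer(tapply(records$sample_id, gene,
                                      function(s) length(unique(s)))),
    stringsAsFactors = FALSE
  )
  out$cds_length <- gene_lengths$cds_length[match(out$gene, gene_lengths$gene)]
  out$normalized_count <- out$mutation_count / out$cds_length
  out$frequency_pct <- 100 * out$patient_count / cohort_size
  rownames(out) <- NULL
  attr(out, "skipped_genes") <- skipped
  out
}

# Length-proportional mutation probabilities over the annotation universe.
length_probs <- function(gene_lengths) {
  p <- gene_lengths$cds_length / sum(as.numeric(gene_lengths$cds_length))
  names(p) <- gene_lengths$gene
  p
}

#' Binomial burden test with CDS-length success probabilities
#'
#' Per tested gene, `P(X >= x)` under `Binomial(N, L_gene / sum L_j)`, where
#' `N` is the cohort's total mutation count (including synonymous) and the
#' length sum runs over the full annotation universe.
#'
#' @param stats per-gene table from [gene_mutation_stats()].
#' @param n_total total mutations in the cohort, including synonymous.
#' @param gene_lengths annotation universe (`gene`, `cds_length`).
#' @return named numeric vector of upper-tail p-values.
#' @export
som_binomial_test <- function(stats, n_total, gene_lengths) {
  if (n_total < max(0L, stats$mutation_count)) {
    stop("`n_total` cannot be smaller than any per-gene count", call. = FALSE)
  }
  probs <- length_probs(gene_lengths)
  p <- vapply(seq_len(nrow(stats)), function(i) {
    binomial_tail_p(stats$mutation_count[i], n_total,
                    unname(probs[stats$gene[i]]))
  }, numeric(1))
  names(p) <- stats$gene
  p
}

#' Multinomial permutation null for mutation counts
#'
#' Simulates the cohort's `n_total` mutations falling over the annotation
#' universe with length-proportional probabilities, preserving the total in
#' every draw, and returns the add-one empirical p-value of each tested
#' gene's observed count against its marginal null. A per-gene independent
#' binomial sampler (`method = "binomial"`) is available; the per-gene
#' marginals are identical in distribution but draws are not coupled across
#' genes.
#'
#' @inheritParams som_binomial_test
#' @param n_simulations number of simulated cohorts (default 10000).
#' @param seed integer seed.
#' @param method `"multinomial"` (default, exact joint null) or `"binomial"`.
#' @return named numeric vector of empirical p-values.
#' @export
som_multinomial_permutation <- function(stats, n_total, gene_lengths,
                                        n_simulations = 10000, seed = 1L,
                                        method = c("multinomial", "binomial")) {
  method <- match.arg(method)
  if (n_simulations < 1) stop("`n_simulations` must be >= 1", call. = FALSE)
  probs <- length_probs(gene_lengths)
  set.seed(seed)
  idx <- match(stats$gene, gene_lengths$gene)
  if (anyNA(idx)) stop("tested gene missing from annotation", call. = FALSE)
  if (method == "multinomial") {
    draws <- stats::rmultinom(n_simulations, size = n_total, prob = probs)
    p <- vapply(seq_len(nrow(stats)), function(i) {
      empirical_p(stats$mutation_count[i], draws[idx[i], ])
    }, numeric(1))
  } else {
    p <- vapply(seq_len(nrow(stats)), function(i) {
      null_counts <- stats::rbinom(n_simulations, n_total, probs[idx[i]])
      empirical_p(stats$mutation_count[i], null_counts)
    }, numeric(1))
  }
  names(p) <- stats$gene
  p
}

#' Composite mutation score
#'
#' Length-normalized burden (mutations per bp) multiplied by the cohort
#' frequency in percent, balancing mutation amplitude against prevalence.
#'
#' @param stats per-gene table from [gene_mutation_stats()].
#' @return named numeric vector of non-negative scores.
#' @export
mutation_score <- function(stats) {
  score <- stats$normalized_count * stats$frequency_pct
  names(score) <- stats$gene
  score
}

#' Full somatic-mutation risk-gene analysis for one stratum
#'
#' Non-synonymous filtering, per-gene burden statistics, binomial and
#' multinomial-permutation testing with BH correction, mutation scoring, and
#' dual-gate risk-gene selection (shared with the copy-number module).
#'
#' @param mutations MAF-style data.frame (`sample_id`, `gene`,
#'   `variant_classification`); `sample_id` should already be a patient
#'   identifier (see [patient_from_barcode()]).
#' @param gene_lengths annotation universe (`gene`, `cds_length`).
#' @param cohort_size number of patients in the stratum; defaults to the
#'   number of unique `sample_id`s in `mutations`.
#' @inheritParams select_risk_genes
#' @param n_simulations simulated cohorts for the multinomial null
#'   (default 10000).
#' @param seed integer seed.
#' @param null_method passed to [som_multinomial_permutation()].
#' @return list with `stats`, `risk`, `n_total` and the parameters used.
#' @export
analyze_som <- function(mutations, gene_lengths, cohort_size = NULL,
                        alpha = 0.05, n_simulations = 10000, seed = 1L,
                        cutoff_method = "percentile", cutoff_param = 95,
                        cutoff_scope = "all", null_method = "multinomial",
                        stratum = NA_character_) {
  if (is.null(cohort_size)) cohort_size <- length(unique(mutations$sample_id))
  flt <- filter_nonsynonymous(mutations)
  stats <- gene_mutation_stats(flt$records, gene_lengths, cohort_size)
  if (nrow(stats) == 0L) {
    warning("no non-synonymous mutations in annotated genes", call. = FALSE)
    risk <- structure(list(genes = character(0), score_cutoff = NA_real_,
                           selection_method = "none", alpha = alpha,
                           stratum = stratum, source = "somatic_mutation",
                           table = stats),
                      class = "risk_gene_set")
    return(list(stats = stats, risk = risk, n_total = flt$n_total,
                params = list(alpha = alpha, n_simulations = n_simulations,
                              seed = seed)))
  }
  stats$score <- as.numeric(mutation_score(stats))
  stats$p_binomial <- as.numeric(
    som_binomial_test(stats, flt$n_total, gene_lengths))
  stats$p_empirical <- as.numeric(
    som_multinomial_permutation(stats, flt$n_total, gene_lengths,
                                n_simulations, seed, null_method))
  stats$q_binomial <- as.numeric(bh_fdr(stats$p_binomial))
  stats$q_empirical <- as.numeric(bh_fdr(stats$p_empirical))

  risk <- select_risk_genes(stats, score_col = "score", alpha = alpha,
                            cutoff_method = cutoff_method,
                            cutoff_param = cutoff_param,
                            cutoff_scope = cutoff_scope,
                            stratum = stratum, source = "somatic_mutation")
  list(stats = stats, risk = risk, n_total = flt$n_total,
       params = list(alpha = alpha, n_simulations = n_simulations,
                     seed = seed, cutoff_method = cutoff_method,
                     cutoff_param = cutoff_param, cutoff_scope = cutoff_scope,
                     null_method = null_method))
}
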