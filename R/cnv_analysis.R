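#' @title Gene-level copy-number alteration analysis
#' @name cnv_analysis
#' @description
#' Per-stratum, per-direction identification of significantly amplified or
#' deleted genes from an integer gene-level copy-number table. High-level
#' events (amplification: CNV > 4; deletion: CNV = 0) are tested against the
#' stratum's genome-wide background event rate with a binomial test and
#' against a pooled-resampling permutation null, both FDR-corrected; genes
#' passing both gates are ranked by a GISTIC-like amplitude-times-frequency
#' score and thresholded to a final risk-gene set.
NULL

AMP_HIGH_CNV <- 4L   # high-level amplification: CNV > 4
DEL_HIGH_CNV <- 1L   # high-level deletion: CNV < 1 (i.e. CNV = 0 for integers)
AMP_CAP_CNV <- 7L    # amplitude cap so outliers do not dominate the score

check_direction <- function(direction) {
  match.arg(direction, c("amplification", "deletion"))
}

check_cnv_table <- function(cnv) {
  need <- c("sample_id", "gene", "copy_number")
  if (!is.data.frame(cnv) || !all(need %in% names(cnv)) || nrow(cnv) == 0L) {
    stop("`cnv` must be a non-empty data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  cn <- cnv$copy_number
  if (anyNA(cn) || any(cn < 0) || any(cn != floor(cn))) {
    stop("copy numbers must be non-negative integers", call. = FALSE)
  }
  invisible(cnv)
}

#' Per-sample amplitude contribution of a copy-number value
#'
#' Amplification amplitude is `log2(min(CNV, 7)) - 1`, which is zero at the
#' diploid baseline CNV = 2 and capped at CNV = 7; deletion intensity is +1
#' for a single-copy loss (CNV = 1) and +2 for a homozygous deletion
#' (CNV = 0). Values on the unaltered side contribute zero.
#'
#' @param copy_number integer vector of copy-number values.
#' @param direction `"amplification"` or `"deletion"`.
#' @param log_rule amplification log transform: `"log2_minus_1"` (default,
#'   `log2(CNV) - 1`, the log2(CN/2) convention) or `"log2_shifted"`
#'   (`log2(CNV - 1)`); both are zero at CNV = 2.
#' @return numeric vector of per-observation amplitude contributions.
#' @export
cnv_amplitude <- function(copy_number, direction,
                          log_rule = c("log2_minus_1", "log2_shifted")) {
  direction <- check_direction(direction)
  log_rule <- match.arg(log_rule)
  amp <- numeric(length(copy_number))
  if (direction == "amplification") {
    i <- copy_number > 2
    capped <- pmin(copy_number[i], AMP_CAP_CNV)
    amp[i] <- if (log_rule == "log2_minus_1") log2(capped) - 1 else log2(capped - 1)
  } else {
    amp[copy_number == 1] <- 1
    amp[copy_number == 0] <- 2
  }
  amp
}

#' Accumulate per-gene copy-number event and amplitude statistics
#'
#' For each gene: the high-level event count (amplification CNV > 4,
#' deletion CNV = 0), the summed amplitude over altered samples, the altered
#' sample count that serves as the amplitude-average denominator, and the
#' high-level event frequency in percent.
#'
#' @param cnv data.frame with columns `sample_id`, `gene`, `copy_number`
#'   (one row per gene x sample observation).
#' @param direction `"amplification"` or `"deletion"`.
#' @param amplitude_scope which samples feed the amplitude accumulator:
#'   `"altered"` (default; any deviation from diploid on the relevant side,
#'   CNV > 2 or CNV < 2) or `"high"` (high-level events only).
#' @param log_rule passed to [cnv_amplitude()].
#' @return data.frame with one row per gene: `gene`, `n_samples`,
#'   `high_event_count`, `amplitude_sum`, `altered_sample_count`,
#'   `event_frequency_pct`, `direction`.
#' @export
call_cnv_events <- function(cnv, direction,
                            amplitude_scope = c("altered", "high"),
                            log_rule = c("log2_minus_1", "log2_shifted")) {
  check_cnv_table(cnv)
  direction <- check_direction(direction)
  amplitude_scope <- match.arg(amplitude_scope)
  log_rule <- match.arg(log_rule)

  cn <- cnv$copy_number
  high <- if (direction == "amplification") cn > AMP_HIGH_CNV else cn < DEL_HIGH_CNV
  altered <- if (direction == "amplification") cn > 2 else cn < 2
  if (amplitude_scope == "high") altered <- high
  amp <- cnv_amplitude(cn, direction, log_rule)
  amp[!altered] <- 0

  gene <- factor(cnv$gene, levels = unique(cnv$gene))
  out <- data.frame(
    gene = levels(gene),
    n_samples = as.integer(tapply(cnv$sample_id, gene,
                                  function(s) length(unique(s)))),
    high_event_count = as.integer(tapply(high, gene, sum)),
    amplitude_sum = as.numeric(tapply(amp, gene, sum)),
    altered_sample_count = as.integer(tapply(altered, gene, sum)),
    stringsAsFactors = FALSE
  )
  out$event_frequency_pct <- 100 * out$high_event_count / out$n_samples
  out$direction <- direction
  rownames(out) <- NULL
  out
}

#' Genome-wide background rate of high-level copy-number events
#'
#' The fraction of all pooled copy-number observations in a stratum (every
#' gene x sample value) beyond the high-level threshold for the requested
#' direction. This is the binomial null success probability: each gene is
#' tested against the cohort's overall genomic instability.
#'
#' @param copy_numbers integer vector of pooled copy-number observations, or a
#'   copy-number data.frame (its `copy_number` column is used).
#' @param direction `"amplification"` or `"deletion"`.
#' @return background event rate in `[0, 1]`.
#' @export
background_rate <- function(copy_numbers, direction) {
  direction <- check_direction(direction)
  if (is.data.frame(copy_numbers)) copy_numbers <- copy_numbers$copy_number
  if (length(copy_numbers) == 0L) stop("empty copy-number pool", call. = FALSE)
  if (anyNA(copy_numbers) || any(copy_numbers < 0)) {
    stop("copy numbers must be non-negative", call. = FALSE)
  }
  if (direction == "amplification") {
    mean(copy_numbers > AMP_HIGH_CNV)
  } else {
    mean(copy_numbers < DEL_HIGH_CNV)
  }
}

#' Binomial significance of per-gene high-level event counts
#'
#' @param stats per-gene table from [call_cnv_events()].
#' @param p_null background event rate from [background_rate()] on the same
#'   stratum and direction.
#' @return named numeric vector of upper-tail binomial p-values, one per gene.
#' @export
cnv_binomial_test <- function(stats, p_null) {
  p <- vapply(seq_len(nrow(stats)), function(i) {
    binomial_tail_p(stats$high_event_count[i], stats$n_samples[i], p_null)
  }, numeric(1))
  names(p) <- stats$gene
  p
}

#' Permutation null for high-level event counts
#'
#' Draws `n_samples` copy-number values with replacement from the pooled
#' stratum observations, `n_permutations` times, and records the count of
#' high-level events per draw. The same null applies to every gene in the
#' stratum/direction, so it is built once and reused.
#'
#' @param pooled_values integer vector of all copy-number observations in the
#'   stratum.
#' @param n_samples cohort size (values drawn per permutation).
#' @param direction `"amplification"` or `"deletion"`.
#' @param n_permutations number of permutations (default 1000).
#' @param seed integer seed; identical seed and inputs give identical nulls.
#' @return integer vector of length `n_permutations` of null event counts.
#' @export
cnv_permutation_null <- function(pooled_values, n_samples, direction,
                                 n_permutations = 1000, seed = 1L) {
  direction <- check_direction(direction)
  if (n_permutations < 1) stop("`n_permutations` must be >= 1", call. = FALSE)
  if (length(pooled_values) == 0L) stop("empty copy-number pool", call. = FALSE)
  high <- if (direction == "amplification") {
    pooled_values > AMP_HIGH_CNV
  } else {
    pooled_values < DEL_HIGH_CNV
  }
  set.seed(seed)
  idx <- sample.int(length(pooled_values), n_samples * n_permutations,
                    replace = TRUE)
  as.integer(colSums(matrix(high[idx], nrow = n_samples)))
}

#' Empirical permutation p-values for per-gene event counts
#'
#' @inheritParams cnv_permutation_null
#' @param stats per-gene table from [call_cnv_events()].
#' @return named numeric vector of add-one empirical p-values.
#' @export
cnv_permutation_test <- function(stats, pooled_values, n_samples, direction,
                                 n_permutations = 1000, seed = 1L) {
  null_counts <- cnv_permutation_null(pooled_values, n_samples, direction,
                                      n_permutations, seed)
  p <- vapply(stats$high_event_count, empirical_p, numeric(1),
              counts = null_counts)
  names(p) <- stats$gene
  p
}

#' GISTIC-like composite alteration score
#'
#' Mean amplitude over altered samples multiplied by the high-level event
#' frequency in percent. Genes with no altered samples score zero. For
#' amplification the amplitude is the capped log2-adjusted copy number; for
#' deletion it is the +1/+2 loss intensity, and the frequency term counts
#' homozygous deletions (CNV = 0).
#'
#' @param stats per-gene table from [call_cnv_events()].
#' @return named numeric vector of non-negative scores.
#' @export
gistic_like_score <- function(stats) {
  score <- ifelse(stats$altered_sample_count > 0,
                  stats$amplitude_sum / stats$altered_sample_count *
                    stats$event_frequency_pct,
                  0)
  names(score) <- stats$gene
  score
}

#' Select risk genes by dual significance and score cutoff
#'
#' Retains genes with FDR-adjusted significance in both the parametric
#' (binomial / hypergeometric) and permutation tests, then applies a
#' data-driven score threshold. The threshold is either a percentile of the
#' score distribution or the knee (maximum perpendicular distance from the
#' chord) of the sorted score curve; the reference distribution is, by
#' default, the scores of all tested genes, so the cutoff marks where scores
#' leave the bulk background distribution.
#'
#' @param stats data.frame with columns `gene`, `q_binomial`, `q_empirical`
#'   and a score column. Rows with `NA` q-values are treated as untested.
#' @param score_col name of the score column (default `"score"`).
#' @param alpha FDR threshold applied to both q-values (default 0.05).
#' @param cutoff_method `"percentile"` (default) or `"knee"`.
#' @param cutoff_param percentile in `[0, 100]` when
#'   `cutoff_method = "percentile"` (default 95); ignored for `"knee"`.
#' @param cutoff_scope score distribution used to place the cutoff: `"all"`
#'   tested genes (default) or only the `"significant"` (dual-gated) genes.
#' @param stratum,source optional labels recorded on the result.
#' @return object of class `risk_gene_set`: a list with `genes` (character),
#'   `score_cutoff`, `selection_method`, `alpha`, `stratum`, `source`, and
#'   `table` (the dual-significant rows with a `selected` flag).
#' @export
select_risk_genes <- function(stats, score_col = "score", alpha = 0.05,
                              cutoff_method = c("percentile", "knee"),
                              cutoff_param = 95,
                              cutoff_scope = c("all", "significant"),
                              stratum = NA_character_,
                              source = NA_character_) {
  cutoff_method <- match.arg(cutoff_method)
  cutoff_scope <- match.arg(cutoff_scope)
  if (!score_col %in% names(stats)) {
    stop("score column `", score_col, "` not found", call. = FALSE)
  }
  score <- stats[[score_col]]
  sig <- !is.na(stats$q_binomial) & !is.na(stats$q_empirical) &
    stats$q_binomial < alpha & stats$q_empirical < alpha

  method_label <- if (cutoff_method == "percentile") {
    sprintf("percentile_%g_%s", cutoff_param, cutoff_scope)
  } else {
    sprintf("knee_%s", cutoff_scope)
  }

  empty <- function(cutoff) {
    structure(list(genes = character(0), score_cutoff = cutoff,
                   selection_method = method_label, alpha = alpha,
                   stratum = stratum, source = source,
                   table = stats[sig, , drop = FALSE]),
              class = "risk_gene_set")
  }
  if (!any(sig)) {
    warning("no gene passed the dual q < ", alpha, " gate", call. = FALSE)
    return(empty(NA_real_))
  }

  ref <- if (cutoff_scope == "significant") score[sig] else
    score[!is.na(stats$q_binomial)]
  cutoff <- if (sum(sig) == 1L) {
    # a single dual-significant gene defines a degenerate score distribution
    # and is retained regardless of the cutoff rule
    score[sig]
  } else if (cutoff_method == "percentile") {
    as.numeric(stats::quantile(ref, cutoff_param / 100, names = FALSE))
  } else {
    knee_cutoff(ref)
  }

  keep <- sig & score >= cutoff
  tab <- stats[sig, , drop = FALSE]
  tab$selected <- score[sig] >= cutoff
  structure(list(genes = stats$gene[keep], score_cutoff = cutoff,
                 selection_method = method_label, alpha = alpha,
                 stratum = stratum, source = source, table = tab),
            class = "risk_gene_set")
}

# Knee of the sorted (descending) score curve: the point of maximum
# perpendicular distance from the chord joining the first and last scores.
knee_cutoff <- function(scores) {
  y <- sort(scores, decreasing = TRUE)
  k <- length(y)
  if (k < 3L || y[1] == y[k]) return(min(y))
  x <- seq_len(k)
  # distance from (x_i, y_i) to the line through (1, y_1) and (k, y_k)
  d <- abs((y[k] - y[1]) * (x - 1) - (k - 1) * (y - y[1])) /
    sqrt((y[k] - y[1])^2 + (k - 1)^2)
  y[which.max(d)]
}

#' @export
print.risk_gene_set <- function(x, ...) {
  cat("Risk gene set", if (!is.na(x$stratum)) paste0("[", x$stratum, "]"),
      if (!is.na(x$source)) paste0("(", x$source, ")"), "\n")
  cat("  dual-significant genes:", nrow(x$table),
      "| selected:", length(x$genes), "\n")
  cat("  score cutoff:", format(x$score_cutoff, digits = 4),
      "(", x$selection_method, "), alpha =", x$alpha, "\n")
  if (length(x$genes)) {
    cat("  genes:", paste(utils::head(x$genes, 20), collapse = ", "),
        if (length(x$genes) > 20) "...", "\n")
  }
  invisible(x)
}

#' Full copy-number risk-gene analysis for one stratum and direction
#'
#' Runs event calling, background-rate estimation, binomial and permutation
#' testing, BH correction, GISTIC-like scoring and risk-gene selection in one
#' call. Only genes with at least one high-level event are tested (genes with
#' zero events carry p = 1 and no evidence; leaving them out keeps the FDR
#' correction on the informative tests), but every gene is scored and
#' reported.
#'
#' @inheritParams call_cnv_events
#' @inheritParams select_risk_genes
#' @param n_permutations permutations for the pooled-resampling null
#'   (default 1000).
#' @param seed integer seed for the permutation null.
#' @return list with `stats` (per-gene table: event accumulators, p- and
#'   q-values, `score`), `risk` (a [select_risk_genes()] result), `p_null`
#'   (background rate), `null_counts` (permutation null) and the parameters
#'   used.
#' @export
analyze_cnv <- function(cnv, direction, alpha = 0.05, n_permutations = 1000,
                        seed = 1L, cutoff_method = "percentile",
                        cutoff_param = 95, cutoff_scope = "all",
                        amplitude_scope = "altered",
                        log_rule = "log2_minus_1",
                        stratum = NA_character_) {
  direction <- check_direction(direction)
  stats <- call_cnv_events(cnv, direction, amplitude_scope, log_rule)
  p_null <- background_rate(cnv, direction)
  n_cohort <- length(unique(cnv$sample_id))
  null_counts <- cnv_permutation_null(cnv$copy_number, n_cohort, direction,
                                      n_permutations, seed)

  stats$score <- as.numeric(gistic_like_score(stats))
  stats$p_binomial <- as.numeric(cnv_binomial_test(stats, p_null))
  stats$p_empirical <- vapply(stats$high_event_count, empirical_p, numeric(1),
                              counts = null_counts)
  tested <- stats$high_event_count >= 1L
  stats$q_binomial <- NA_real_
  stats$q_empirical <- NA_real_
  if (any(tested)) {
    stats$q_binomial[tested] <- bh_fdr(stats$p_binomial[tested])
    stats$q_empirical[tested] <- bh_fdr(stats$p_empirical[tested])
  }

  risk <- select_risk_genes(stats, score_col = "score", alpha = alpha,
                            cutoff_method = cutoff_method,
                            cutoff_param = cutoff_param,
                            cutoff_scope = cutoff_scope,
                            stratum = stratum,
                            source = paste0("cnv_", direction))
  list(stats = stats, risk = risk, p_null = p_null, null_counts = null_counts,
       params = list(direction = direction, alpha = alpha,
                     n_permutations = n_permutations, seed = seed,
                     cutoff_method = cutoff_method,
                     cutoff_param = cutoff_param,
                     cutoff_scope = cutoff_scope,
                     amplitude_scope = amplitude_scope,
                     log_rule = log_rule))
}
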