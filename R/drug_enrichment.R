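#' @title Drug-target enrichment against risk genes
#' @name drug_enrichment
#' @description
#' Ranks drugs by the enrichment of their target sets in the validated
#' risk-gene set (direct risk genes plus validated PPI neighbors), using a
#' right-tailed hypergeometric test over the druggable-gene universe and an
#' empirical permutation test that resamples risk-set-sized gene sets from
#' the same universe. Both p-vectors are BH-corrected across drugs and a
#' drug is retained only when significant in both; retained drugs are
#' classified as direct (targeting a risk gene), indirect (targeting a
#' validated neighbor) or both.
NULL

#' Build the druggable-gene universe and per-drug target sets
#'
#' @param interactions data.frame with columns `drug_id`, `drug_name`,
#'   `gene` (one row per drug-gene interaction; duplicates are collapsed).
#' @return list with `universe` (character vector, all genes with at least
#'   one interaction), `targets` (named list drug_id -> unique target
#'   symbols) and `drug_names` (named character vector drug_id -> name).
#' @export
build_universe <- function(interactions) {
  need <- c("drug_id", "drug_name", "gene")
  if (!is.data.frame(interactions) || !all(need %in% names(interactions)) ||
      nrow(interactions) == 0L) {
    stop("`interactions` must be a non-empty data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  ia <- interactions[!duplicated(interactions[c("drug_id", "gene")]), ,
                     drop = FALSE]
  targets <- lapply(split(ia$gene, ia$drug_id), unique)
  nm <- ia$drug_name[!duplicated(ia$drug_id)]
  names(nm) <- ia$drug_id[!duplicated(ia$drug_id)]
  list(universe = sort(unique(ia$gene)), targets = targets,
       drug_names = nm[names(targets)])
}

#' Right-tailed hypergeometric enrichment of one drug's targets
#'
#' `P(X >= x)` for the overlap `x` between the drug's targets and the risk
#' set, given `K` targets, `n = |risk  universe|` risk genes, and `M`
#' universe genes. Normalising by each drug's target count `K` controls for
#' medications with broad target profiles.
#'
#' @param drug_targets character vector of the drug's target symbols
#'   (subset of `universe`).
#' @param risk_set character vector of risk-gene symbols; intersected with
#'   the universe before testing.
#' @param universe character vector of all druggable genes.
#' @return the upper-tail hypergeometric p-value.
#' @export
drug_hypergeom_test <- function(drug_targets, risk_set, universe) {
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  targets <- intersect(unique(drug_targets), universe)
  risk <- intersect(unique(risk_set), universe)
  x <- length(intersect(targets, risk))
  hypergeom_tail_p(x, M = length(universe), K = length(targets),
                   n = length(risk))
}

# Index matrix of uniformly resampled risk sets: n rows (set members) by
# n_permutations columns, sampled without replacement within each column.
sample_risk_sets <- function(M, n, n_permutations, seed) {
  set.seed(seed)
  vapply(seq_len(n_permutations), function(i) sample.int(M, n),
         integer(n))
}

#' Permutation enrichment of one drug's targets
#'
#' Samples `n_permutations` gene sets of the risk-set size uniformly without
#' replacement from the universe and returns the add-one empirical p-value
#' of the observed overlap. Guards against enrichment driven purely by
#' highly connected genes or target-set size.
#'
#' @inheritParams drug_hypergeom_test
#' @param n_permutations number of resampled sets (default 100000).
#' @param seed integer seed.
#' @return add-one empirical p-value in `[1/(N+1), 1]`.
#' @export
drug_permutation_test <- function(drug_targets, risk_set, universe,
                                  n_permutations = 100000, seed = 1L) {
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  targets <- intersect(unique(drug_targets), universe)
  risk <- intersect(unique(risk_set), universe)
  n <- length(risk)
  if (n > length(universe)) stop("risk set larger than universe", call. = FALSE)
  if (n == 0L) return(1)
  x_obs <- length(intersect(targets, risk))
  idx <- sample_risk_sets(length(universe), n, n_permutations, seed)
  memb <- universe %in% targets
  counts <- colSums(matrix(memb[idx], nrow = n))
  empirical_p(x_obs, counts)
}

#' Enrich all drugs against the validated risk set
#'
#' Runs the hypergeometric and permutation tests for every drug against the
#' union of validated direct risk genes and validated neighbors, applies BH
#' correction across drugs separately per test, gates on both q-values, and
#' classifies retained drugs by which part of the risk set they hit. All
#' drugs are returned (with a `retained` flag) for audit; the permutation
#' null reuses one resampled-set ensemble across drugs.
#'
#' @param interactions drug-gene interaction data.frame
#'   (see [build_universe()]).
#' @param risk_direct character vector of validated direct risk genes.
#' @param risk_neighbors character vector of validated neighbor genes.
#' @param alpha dual FDR threshold (default 0.05).
#' @param n_permutations permutations for the empirical test
#'   (default 100000).
#' @param seed integer seed.
#' @return list with `results` (data.frame: `drug_id`, `drug_name`, `K`,
#'   `x`, `p_hypergeom`, `p_empirical`, `q_hypergeom`, `q_empirical`,
#'   `retained`, `classification`, `overlap_direct`, `overlap_neighbor`,
#'   `overlapping_genes`, ranked by hypergeometric q then p), `universe`,
#'   `risk_set`, `n_risk` and the parameters used.
#' @export
enrich_all <- function(interactions, risk_direct, risk_neighbors = character(0),
                       alpha = 0.05, n_permutations = 100000, seed = 1L) {
  uni <- build_universe(interactions)
  risk_direct <- intersect(unique(risk_direct), uni$universe)
  risk_neighbors <- intersect(unique(risk_neighbors), uni$universe)
  risk_set <- union(risk_direct, risk_neighbors)
  n <- length(risk_set)
  M <- length(uni$universe)

  drug_ids <- names(uni$targets)
  empty <- data.frame(drug_id = character(0), drug_name = character(0),
                      K = integer(0), x = integer(0),
                      p_hypergeom = numeric(0), p_empirical = numeric(0),
                      q_hypergeom = numeric(0), q_empirical = numeric(0),
                      retained = logical(0), classification = character(0),
                      overlap_direct = character(0),
                      overlap_neighbor = character(0),
                      overlapping_genes = character(0))
  if (n == 0L) {
    warning("risk set is empty after intersecting with the drug universe",
            call. = FALSE)
    return(list(results = empty, universe = uni$universe,
                risk_set = risk_set, n_risk = 0L,
                params = list(alpha = alpha,
                              n_permutations = n_permutations, seed = seed)))
  }

  idx <- sample_risk_sets(M, n, n_permutations, seed)
  res <- lapply(drug_ids, function(d) {
    targets <- uni$targets[[d]]
    overlap <- intersect(targets, risk_set)
    x <- length(overlap)
    p_h <- hypergeom_tail_p(x, M = M, K = length(targets), n = n)
    memb <- uni$universe %in% targets
    counts <- colSums(matrix(memb[idx], nrow = n))
    p_e <- empirical_p(x, counts)
    od <- intersect(overlap, risk_direct)
    on_ <- intersect(overlap, risk_neighbors)
    data.frame(drug_id = d, drug_name = unname(uni$drug_names[d]),
               K = length(targets), x = x, p_hypergeom = p_h,
               p_empirical = p_e,
               overlap_direct = paste(od, collapse = ";"),
               overlap_neighbor = paste(on_, collapse = ";"),
               overlapping_genes = paste(overlap, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$q_hypergeom <- as.numeric(bh_fdr(res$p_hypergeom))
  res$q_empirical <- as.numeric(bh_fdr(res$p_empirical))
  res$retained <- res$q_hypergeom < alpha & res$q_empirical < alpha & res$x > 0
  res$classification <- ifelse(
    !res$retained, "",
    ifelse(nzchar(res$overlap_direct) & nzchar(res$overlap_neighbor), "both",
           ifelse(nzchar(res$overlap_direct), "direct", "indirect")))
  res <- res[order(res$q_hypergeom, res$p_hypergeom, -res$x), , drop = FALSE]
  rownames(res) <- NULL
  cols <- c("drug_id", "drug_name", "K", "x", "p_hypergeom", "p_empirical",
            "q_hypergeom", "q_empirical", "retained", "classification",
            "overlap_direct", "overlap_neighbor", "overlapping_genes")
  list(results = res[, cols], universe = uni$universe, risk_set = risk_set,
       n_risk = n,
       params = list(alpha = alpha, n_permutations = n_permutations,
                     seed = seed))
}
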