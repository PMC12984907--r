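#' @title Synthetic cohort generator with planted signal
#' @name synthetic_data
#' @description
#' Generates every input the pipeline consumes -- gene-level copy-number
#' tables, MAF-style mutation records with CDS lengths, HPV labels, scored
#' PPI edges, drug-gene interactions and abstract corpora -- with
#' controllable planted signal and a ground-truth record, so each stage and
#' the end-to-end run can be verified offline. Signal is stylized (it
#' matches the pipeline's statistical assumptions, not empirical tumor
#' spectra): amplified/deleted genes with fixed level and carrier fraction,
#' length-biased mutation drivers, high-score planted PPI neighbors,
#' planted true-positive drugs, and abstracts mentioning planted genes.
NULL

#' Simulation configuration
#'
#' Central parameter object for all generators. The defaults define the
#' "demo cohort": 500 genes x 100 samples, 10 amplified genes planted at
#' copy number 6 in 30% of samples, 5 homozygous-deleted genes in 30% of
#' samples, 5 mutation drivers at 10x their length-expected rate, 2 planted
#' PPI neighbors per planted gene, 200 decoy drugs plus 2 planted
#' true-positive drugs, and 500 abstracts. The default total mutation count
#' (3300) reproduces a typical head-and-neck cohort rate of roughly 33
#' somatic mutations per case.
#'
#' @param seed master integer seed; every generator derives its stream from
#'   it, so a fixed config is fully reproducible.
#' @param n_genes,n_samples cohort dimensions.
#' @param hpv_positive_fraction fraction of samples labeled HPV-positive.
#' @param amp_spec data.frame (`gene_index`, `level`, `carrier_fraction`)
#'   of planted amplifications; `NULL` disables planting.
#' @param del_spec same layout for planted homozygous deletions.
#' @param background_cnv_probs probability mass over copy numbers 0..7 for
#'   background observations (default: 0.972 at the diploid value, 0.004 on
#'   each other state, so background event rates are non-degenerate).
#' @param driver_spec data.frame (`gene_index`, `multiplier`,
#'   `min_patient_fraction`) of planted mutation drivers.
#' @param n_total_mutations total MAF rows generated (synonymous included).
#' @param synonymous_fraction probability a mutation is Silent.
#' @param gene_length_range CDS length range in bp (uniform integer draw).
#' @param ppi_density background edge probability between background genes.
#' @param neighbors_per_seed planted high-score neighbors per planted gene.
#' @param n_drugs number of decoy drugs.
#' @param targets_per_drug_range decoy target-set size range.
#' @param n_abstracts total abstracts in the corpus.
#' @param mentions_per_gene abstracts mentioning each planted gene/neighbor.
#' @param abstract_year_range publication-year range for filler abstracts
#'   (straddles 2000 so the year filter is exercised).
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L, n_genes = 500L, n_samples = 100L,
                       hpv_positive_fraction = 0.5,
                       amp_spec = data.frame(gene_index = 1:10, level = 6L,
                                             carrier_fraction = 0.3),
                       del_spec = data.frame(gene_index = 11:15, level = 0L,
                                             carrier_fraction = 0.3),
                       background_cnv_probs = c(0.004, 0.004, 0.972, 0.004,
                                                0.004, 0.004, 0.004, 0.004),
                       driver_spec = data.frame(gene_index = 16:20,
                                                multiplier = 10,
                                                min_patient_fraction = 0.1),
                       n_total_mutations = 3300L,
                       synonymous_fraction = 0.3,
                       gene_length_range = c(500L, 5000L),
                       ppi_density = 0.01,
                       neighbors_per_seed = 2L,
                       n_drugs = 200L,
                       targets_per_drug_range = c(2L, 8L),
                       n_abstracts = 500L,
                       mentions_per_gene = 3L,
                       abstract_year_range = c(1995L, 2024L)) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_samples = as.integer(n_samples),
              hpv_positive_fraction = hpv_positive_fraction,
              amp_spec = amp_spec, del_spec = del_spec,
              background_cnv_probs = background_cnv_probs,
              driver_spec = driver_spec,
              n_total_mutations = as.integer(n_total_mutations),
              synonymous_fraction = synonymous_fraction,
              gene_length_range = as.integer(gene_length_range),
              ppi_density = ppi_density,
              neighbors_per_seed = as.integer(neighbors_per_seed),
              n_drugs = as.integer(n_drugs),
              targets_per_drug_range = as.integer(targets_per_drug_range),
              n_abstracts = as.integer(n_abstracts),
              mentions_per_gene = as.integer(mentions_per_gene),
              abstract_year_range = as.integer(abstract_year_range))
  stopifnot(cfg$n_genes > 0, cfg$n_samples > 0,
            cfg$hpv_positive_fraction >= 0, cfg$hpv_positive_fraction <= 1,
            abs(sum(cfg$background_cnv_probs) - 1) < 1e-9,
            cfg$synonymous_fraction >= 0, cfg$synonymous_fraction <= 1,
            cfg$ppi_density >= 0, cfg$ppi_density <= 1)
  for (spec in list(cfg$amp_spec, cfg$del_spec, cfg$driver_spec)) {
    if (!is.null(spec) && nrow(spec) &&
        any(spec$gene_index > cfg$n_genes | spec$gene_index < 1)) {
      stop("planted gene indices must lie in 1..n_genes", call. = FALSE)
    }
  }
  class(cfg) <- "sim_config"
  cfg
}

sim_gene_symbols <- function(cfg) sprintf("G%04d", seq_len(cfg$n_genes))
sim_sample_ids <- function(cfg) sprintf("S%03d", seq_len(cfg$n_samples))

#' Planted gene symbols of a configuration
#' @param cfg a [sim_config()].
#' @return list with `amplified`, `deleted`, `drivers` character vectors.
#' @export
sim_truth_genes <- function(cfg) {
  g <- sim_gene_symbols(cfg)
  pick <- function(spec) if (is.null(spec) || !nrow(spec)) character(0) else
    g[spec$gene_index]
  list(amplified = pick(cfg$amp_spec), deleted = pick(cfg$del_spec),
       drivers = pick(cfg$driver_spec))
}

#' Simulate HPV status labels
#'
#' Assigns exactly `round(hpv_positive_fraction * n_samples)` samples to the
#' positive stratum, chosen at random under the config seed.
#'
#' @param cfg a [sim_config()].
#' @return data.frame with columns `sample_id`, `hpv_status`
#'   (`"positive"` / `"negative"`).
#' @export
simulate_labels <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 101L)
  ids <- sim_sample_ids(cfg)
  n_pos <- round(cfg$hpv_positive_fraction * cfg$n_samples)
  pos <- sample(ids, n_pos)
  data.frame(sample_id = ids,
             hpv_status = ifelse(ids %in% pos, "positive", "negative"),
             stringsAsFactors = FALSE)
}

#' Simulate a gene-level copy-number cohort
#'
#' Background observations draw iid integer copy numbers 0..7 from
#' `background_cnv_probs`; each planted gene takes its specified level in
#' exactly `round(carrier_fraction * n_samples)` randomly chosen samples and
#' background values elsewhere. Chromosome and position fields are
#' fabricated deterministically from the gene index.
#'
#' @param cfg a [sim_config()].
#' @return list with `cnv` (long data.frame: `sample_id`, `gene`,
#'   `chromosome`, `start`, `end`, `copy_number`) and `truth`
#'   (see [sim_truth_genes()]).
#' @export
simulate_cnv_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 202L)
  genes <- sim_gene_symbols(cfg)
  samples <- sim_sample_ids(cfg)
  cn <- matrix(sample(0:7, cfg$n_genes * cfg$n_samples, replace = TRUE,
                      prob = cfg$background_cnv_probs),
               nrow = cfg$n_genes)
  plant <- function(spec) {
    if (is.null(spec) || !nrow(spec)) return()
    for (i in seq_len(nrow(spec))) {
      k <- round(spec$carrier_fraction[i] * cfg$n_samples)
      if (k < 1) stop("carrier fraction rounds to zero samples", call. = FALSE)
      carriers <- sample.int(cfg$n_samples, k)
      cn[spec$gene_index[i], carriers] <<- spec$level[i]
    }
  }
  plant(cfg$amp_spec)
  plant(cfg$del_spec)

  chrom <- paste0("chr", (seq_len(cfg$n_genes) - 1L) %% 22L + 1L)
  start <- 1e4L * seq_len(cfg$n_genes)
  cnv <- data.frame(
    sample_id = rep(samples, each = cfg$n_genes),
    gene = rep(genes, times = cfg$n_samples),
    chromosome = rep(chrom, times = cfg$n_samples),
    start = rep(start, times = cfg$n_samples),
    end = rep(start + 5000L, times = cfg$n_samples),
    copy_number = as.integer(cn),
    stringsAsFactors = FALSE
  )
  list(cnv = cnv, truth = sim_truth_genes(cfg))
}

#' Simulate MAF-style mutations and CDS lengths
#'
#' CDS lengths are uniform integers over `gene_length_range`. Exactly
#' `n_total_mutations` events are allocated to genes with probabilities
#' proportional to length times the planted driver multiplier, so background
#' genes follow the length-proportional null the burden test assumes. Each
#' planted driver is guaranteed at least
#' `ceil(min_patient_fraction * n_samples)` events, hitting that many
#' distinct patients (background events are converted to the driver if its
#' multinomial draw falls short, conserving the cohort total). Every event
#' is assigned a patient and a variant classification (Silent with
#' probability `synonymous_fraction`, otherwise a protein-altering class).
#'
#' @param cfg a [sim_config()].
#' @return list with `maf` (data.frame: `sample_id`, `gene`,
#'   `variant_classification`), `gene_lengths` (data.frame: `gene`,
#'   `cds_length`) and `truth`.
#' @export
simulate_maf <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 303L)
  genes <- sim_gene_symbols(cfg)
  samples <- sim_sample_ids(cfg)
  lengths <- sample(cfg$gene_length_range[1]:cfg$gene_length_range[2],
                    cfg$n_genes, replace = TRUE)
  mult <- rep(1, cfg$n_genes)
  if (!is.null(cfg$driver_spec) && nrow(cfg$driver_spec)) {
    mult[cfg$driver_spec$gene_index] <- cfg$driver_spec$multiplier
  }
  prob <- lengths * mult
  gene_idx <- sample.int(cfg$n_genes, cfg$n_total_mutations, replace = TRUE,
                         prob = prob)

  patient <- sample(samples, cfg$n_total_mutations, replace = TRUE)
  silent <- stats::runif(cfg$n_total_mutations) < cfg$synonymous_fraction
  if (!is.null(cfg$driver_spec) && nrow(cfg$driver_spec)) {
    driver_idx <- cfg$driver_spec$gene_index
    for (i in seq_len(nrow(cfg$driver_spec))) {
      gi <- driver_idx[i]
      k <- ceiling(cfg$driver_spec$min_patient_fraction[i] * cfg$n_samples)
      rows <- which(gene_idx == gi)
      short <- k - length(rows)
      if (short > 0) {
        # the planted condition guarantees each driver hits at least
        # min_patient_fraction of patients: convert background events to
        # this driver, conserving the cohort total
        bg_rows <- which(!gene_idx %in% driver_idx)
        take <- sample(bg_rows, short)
        gene_idx[take] <- gi
        rows <- c(rows, take)
      }
      # the guaranteed hits go to distinct patients and must be
      # protein-altering, since only non-synonymous events count as hits
      floor_rows <- rows[seq_len(k)]
      patient[floor_rows] <- sample(samples, k)
      silent[floor_rows] <- FALSE
    }
  }
  nonsyn <- sample(c("Missense_Mutation", "Nonsense_Mutation",
                     "Frame_Shift_Del", "Splice_Site"),
                   cfg$n_total_mutations, replace = TRUE,
                   prob = c(0.7, 0.1, 0.1, 0.1))
  maf <- data.frame(
    sample_id = patient, gene = genes[gene_idx],
    variant_classification = ifelse(silent, "Silent", nonsyn),
    stringsAsFactors = FALSE
  )
  list(maf = maf,
       gene_lengths = data.frame(gene = genes, cds_length = lengths,
                                 stringsAsFactors = FALSE),
       truth = sim_truth_genes(cfg))
}

#' Simulate a scored PPI edge list with planted neighbors
#'
#' Background edges form an Erdos-Renyi graph over the cohort's gene symbols
#' with combined scores uniform on 150..699, so no background edge survives
#' the conventional 700 cutoff. Each planted gene additionally receives
#' `neighbors_per_seed` dedicated neighbor nodes (symbols `NB_<seed>_<k>`)
#' connected at scores 750..950.
#'
#' @param cfg a [sim_config()].
#' @return list with `edges` (data.frame: `gene_a`, `gene_b`,
#'   `combined_score`) and `truth` (`planted_edges` data.frame plus
#'   `neighbors` character vector).
#' @export
simulate_ppi <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 404L)
  genes <- sim_gene_symbols(cfg)
  planted <- unlist(sim_truth_genes(cfg), use.names = FALSE)

  n_bg <- stats::rbinom(1, choose(cfg$n_genes, 2), cfg$ppi_density)
  bg <- if (n_bg > 0) {
    pairs <- matrix(replicate(n_bg, sample.int(cfg$n_genes, 2)), nrow = 2)
    data.frame(gene_a = genes[pairs[1, ]], gene_b = genes[pairs[2, ]],
               combined_score = sample(150:699, n_bg, replace = TRUE),
               stringsAsFactors = FALSE)
  } else {
    data.frame(gene_a = character(0), gene_b = character(0),
               combined_score = integer(0))
  }
  planted_edges <- if (length(planted) && cfg$neighbors_per_seed > 0) {
    do.call(rbind, lapply(planted, function(s) {
      data.frame(gene_a = s,
                 gene_b = paste0("NB_", s, "_", seq_len(cfg$neighbors_per_seed)),
                 combined_score = sample(750:950, cfg$neighbors_per_seed,
                                         replace = TRUE),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(gene_a = character(0), gene_b = character(0),
               combined_score = integer(0))
  }
  list(edges = rbind(bg, planted_edges),
       truth = list(planted_edges = planted_edges,
                    neighbors = unique(planted_edges$gene_b)))
}

#' Simulate a drug-gene interaction table with planted drugs
#'
#' Decoy drugs draw target sets uniformly from the gene universe (cohort
#' genes plus planted neighbor symbols) with sizes uniform over
#' `targets_per_drug_range`. Two planted true-positive drugs are added:
#' `DRUG_TP_DIRECT` targeting planted risk genes and `DRUG_TP_INDIRECT`
#' targeting planted neighbor genes.
#'
#' @param cfg a [sim_config()].
#' @param neighbors character vector of planted neighbor symbols (from
#'   [simulate_ppi()] truth); may be empty.
#' @return list with `interactions` (data.frame: `drug_id`, `drug_name`,
#'   `gene`, `action`) and `truth` (named list drug_id -> target vector).
#' @export
simulate_drug_table <- function(cfg, neighbors = character(0)) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 505L)
  genes <- sim_gene_symbols(cfg)
  universe <- c(genes, neighbors)
  planted <- sim_truth_genes(cfg)
  planted_all <- unlist(planted, use.names = FALSE)

  decoys <- do.call(rbind, lapply(seq_len(cfg$n_drugs), function(i) {
    k <- sample(cfg$targets_per_drug_range[1]:cfg$targets_per_drug_range[2], 1)
    data.frame(drug_id = sprintf("DB%05d", i),
               drug_name = sprintf("Decoyvir-%03d", i),
               gene = sample(universe, k), action = "inhibitor",
               stringsAsFactors = FALSE)
  }))
  truth <- list()
  planted_rows <- NULL
  if (length(planted_all) >= 1) {
    direct_targets <- utils::head(planted_all, 5)
    truth[["DRUG_TP_DIRECT"]] <- direct_targets
    planted_rows <- data.frame(drug_id = "DRUG_TP_DIRECT",
                               drug_name = "Plantedtinib", gene = direct_targets,
                               action = "inhibitor", stringsAsFactors = FALSE)
  }
  if (length(neighbors) >= 1) {
    indirect_targets <- utils::head(neighbors, 5)
    truth[["DRUG_TP_INDIRECT"]] <- indirect_targets
    planted_rows <- rbind(planted_rows, data.frame(
      drug_id = "DRUG_TP_INDIRECT", drug_name = "Plantedmab",
      gene = indirect_targets, action = "inhibitor", stringsAsFactors = FALSE))
  }
  list(interactions = rbind(decoys, planted_rows), truth = truth)
}

#' Simulate an abstract corpus with planted gene mentions
#'
#' Each planted gene and neighbor is mentioned, as a whole token inside a
#' templated evidence sentence, in `mentions_per_gene` distinct post-2000
#' abstracts. Filler abstracts mention no lexicon gene and carry years over
#' `abstract_year_range` (straddling 2000, so the year filter drops some);
#' a few records have empty abstracts or duplicated PMIDs to exercise
#' cleaning.
#'
#' @param cfg a [sim_config()].
#' @param genes_to_mention character vector of symbols to plant (defaults to
#'   all planted genes plus `extra_mentions`).
#' @param extra_mentions additional symbols (e.g. planted PPI neighbors).
#' @return list with `abstracts` (data.frame: `pmid`, `title`, `year`,
#'   `abstract`) and `truth` (named integer vector of planted mention
#'   counts).
#' @export
simulate_abstracts <- function(cfg, genes_to_mention = NULL,
                               extra_mentions = character(0)) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 606L)
  if (is.null(genes_to_mention)) {
    genes_to_mention <- c(unlist(sim_truth_genes(cfg), use.names = FALSE),
                          extra_mentions)
  }
  genes_to_mention <- unique(genes_to_mention)
  templates <- c(
    "Overexpression of %s was associated with poor prognosis in head and neck cancer.",
    "We found that %s drives tumor progression in head and neck squamous carcinoma.",
    "Inhibition of %s reduced proliferation in head and neck cancer cell lines.")
  mention <- do.call(rbind, lapply(genes_to_mention, function(g) {
    data.frame(
      gene = g,
      sentence = sprintf(sample(templates, cfg$mentions_per_gene,
                                replace = TRUE), g),
      stringsAsFactors = FALSE)
  }))
  n_mention <- if (is.null(mention)) 0L else nrow(mention)
  n_filler <- max(cfg$n_abstracts - n_mention, 0L)

  filler_txt <- paste(
    "This retrospective study evaluated treatment outcomes in head and",
    "neck cancer patients. No molecular markers were assessed.")
  abstracts <- data.frame(
    pmid = sprintf("PM%06d", seq_len(n_mention + n_filler)),
    title = c(if (n_mention) paste("Study of", mention$gene,
                                   "in head and neck cancer"),
              rep("Clinical outcomes in head and neck cancer",
                  n_filler)),
    year = c(if (n_mention) sample(2005:2024, n_mention, replace = TRUE),
             sample(cfg$abstract_year_range[1]:cfg$abstract_year_range[2],
                    n_filler, replace = TRUE)),
    abstract = c(if (n_mention) paste(
      "Background information on treatment.", mention$sentence,
      "Further studies are warranted."),
      rep(filler_txt, n_filler)),
    stringsAsFactors = FALSE
  )
  # records that cleaning must remove: empty abstracts and duplicate pmids
  n_bad <- max(2L, round(0.02 * nrow(abstracts)))
  bad <- data.frame(
    pmid = c(sprintf("PMBAD%03d", seq_len(n_bad)),
             utils::head(abstracts$pmid, n_bad)),
    title = "Duplicate or empty record",
    year = 2010L,
    abstract = c(rep("", n_bad), rep(filler_txt, n_bad)),
    stringsAsFactors = FALSE
  )
  out <- rbind(abstracts, bad)
  rownames(out) <- NULL
  truth <- if (n_mention) table(mention$gene) else integer(0)
  list(abstracts = out,
       truth = stats::setNames(as.integer(truth), names(truth)))
}

#' Simulate a complete, mutually consistent input bundle
#'
#' Runs every generator off one configuration: labels, copy-number table,
#' MAF plus CDS lengths, PPI edges, drug table (decoys plus planted drugs
#' whose targets are the planted risk genes / neighbors) and an abstract
#' corpus mentioning all planted genes and neighbors. The gene lexicon for
#' literature extraction is the full symbol space.
#'
#' @param cfg a [sim_config()].
#' @return list with `labels`, `cnv`, `maf`, `gene_lengths`, `ppi_edges`,
#'   `drug_interactions`, `abstracts`, `lexicon` and `truth` (planted genes,
#'   neighbors and drugs).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  labels <- simulate_labels(cfg)
  cnv <- simulate_cnv_cohort(cfg)
  som <- simulate_maf(cfg)
  ppi <- simulate_ppi(cfg)
  drugs <- simulate_drug_table(cfg, neighbors = ppi$truth$neighbors)
  lit <- simulate_abstracts(cfg, extra_mentions = ppi$truth$neighbors)
  list(labels = labels, cnv = cnv$cnv, maf = som$maf,
       gene_lengths = som$gene_lengths, ppi_edges = ppi$edges,
       drug_interactions = drugs$interactions, abstracts = lit$abstracts,
       lexicon = c(sim_gene_symbols(cfg), ppi$truth$neighbors),
       truth = list(genes = sim_truth_genes(cfg),
                    neighbors = ppi$truth$neighbors,
                    planted_edges = ppi$truth$planted_edges,
                    drugs = drugs$truth,
                    mentions = lit$truth))
}
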