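#' @title Readers and writers for the pipeline's file formats
#' @name io
#' @description
#' Thin, validated ingestion of the standard exchange formats -- a long
#' gene-level copy-number TSV (or per-sample GDC-style files), MAF mutation
#' tables, gene-length TSV or GENCODE-style GTF, HPV label TSV, STRING-style
#' PPI link files with optional alias mapping, drug-gene interaction CSV,
#' and abstract corpora in JSONL or CSV -- plus plain-text writers for every
#' stage output (per-gene statistics TSVs, risk-gene lists with JSON
#' sidecars, neighbor maps, evidence tables, ranked drug tables, Sankey
#' edges).
NULL

read_table_checked <- function(path, need, sep = "\t", ...) {
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                          check.names = FALSE, ...)
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(basename(path), " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df
}

#' Read a combined long copy-number TSV
#'
#' Expects a header with `sample_id`, `gene`, `copy_number` (and optionally
#' `chromosome`, `start`, `end`). Copy numbers must be non-negative
#' integers.
#'
#' @param path TSV file path.
#' @return copy-number data.frame.
#' @export
read_cnv_table <- function(path) {
  df <- read_table_checked(path, c("sample_id", "gene", "copy_number"))
  check_cnv_table(df)
}

#' Read per-sample GDC-style copy-number files
#'
#' Each file holds one sample's gene-level values with columns `gene_name`
#' (or `gene`), `chromosome`, `start`, `end`, `copy_number`; `sample_ids`
#' supplies the sample identifier per file (the GDC sample-sheet join).
#'
#' @param files character vector of TSV paths.
#' @param sample_ids character vector, one id per file.
#' @return combined long copy-number data.frame.
#' @export
read_cnv_gdc <- function(files, sample_ids) {
  if (length(files) != length(sample_ids)) {
    stop("`files` and `sample_ids` must have equal length", call. = FALSE)
  }
  out <- lapply(seq_along(files), function(i) {
    df <- utils::read.delim(files[i], stringsAsFactors = FALSE)
    if (!"gene" %in% names(df) && "gene_name" %in% names(df)) {
      df$gene <- df$gene_name
    }
    need <- c("gene", "copy_number")
    miss <- setdiff(need, names(df))
    if (length(miss)) {
      stop(basename(files[i]), " is missing column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    df$sample_id <- sample_ids[i]
    df[c("sample_id", intersect(c("gene", "chromosome", "start", "end",
                                  "copy_number"), names(df)))]
  })
  check_cnv_table(do.call(rbind, out))
}

#' Read an HPV status label TSV
#' @param path TSV with columns `sample_id`, `hpv_status`.
#' @return label data.frame.
#' @export
read_hpv_labels <- function(path) {
  read_table_checked(path, c("sample_id", "hpv_status"))
}

#' Read a MAF file
#'
#' Tab-delimited (optionally gzip-compressed), `#` comment lines skipped.
#' Only `Hugo_Symbol`, `Variant_Classification` and `Tumor_Sample_Barcode`
#' are required; barcodes are reduced to patient identifiers with
#' [patient_from_barcode()].
#'
#' @param path MAF path (`.maf` or `.maf.gz`).
#' @return data.frame with columns `sample_id`, `gene`,
#'   `variant_classification`.
#' @export
read_maf <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("Hugo_Symbol", "Variant_Classification", "Tumor_Sample_Barcode")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(basename(path), " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  data.frame(sample_id = patient_from_barcode(df$Tumor_Sample_Barcode),
             gene = df$Hugo_Symbol,
             variant_classification = df$Variant_Classification,
             stringsAsFactors = FALSE)
}

#' Read a gene-length TSV
#' @param path TSV with columns `gene`, `cds_length`.
#' @return data.frame with positive integer CDS lengths.
#' @export
read_gene_lengths <- function(path) {
  df <- read_table_checked(path, c("gene", "cds_length"))
  if (any(df$cds_length <= 0)) stop("cds_length must be positive", call. = FALSE)
  df
}

#' CDS lengths from a GENCODE-style GTF
#'
#' Per gene, the summed width of its merged (strand-agnostic, 1-based
#' inclusive) CDS intervals, so overlapping CDS records of different
#' transcripts are counted once. Requires the `rtracklayer` and
#' `GenomicRanges` packages.
#'
#' @param path GTF path.
#' @param gene_field attribute naming the gene (default `"gene_name"`).
#' @return data.frame with columns `gene`, `cds_length`.
#' @export
cds_lengths_from_gtf <- function(path, gene_field = "gene_name") {
  if (!requireNamespace("rtracklayer", quietly = TRUE) ||
      !requireNamespace("GenomicRanges", quietly = TRUE)) {
    stop("cds_lengths_from_gtf() requires rtracklayer and GenomicRanges",
         call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "gtf")
  cds <- gr[gr$type == "CDS"]
  if (!length(cds)) stop("no CDS records in ", basename(path), call. = FALSE)
  genes <- S4Vectors::mcols(cds)[[gene_field]]
  GenomicRanges::strand(cds) <- "*"
  by_gene <- GenomicRanges::split(cds, genes)
  merged <- GenomicRanges::reduce(by_gene)
  len <- vapply(GenomicRanges::width(merged), sum, numeric(1))
  data.frame(gene = names(len), cds_length = as.integer(len),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read a STRING-style PPI link file
#'
#' Whitespace- or tab-delimited with header columns `protein1`, `protein2`,
#' `combined_score` (or already-mapped `gene_a`, `gene_b`,
#' `combined_score`). When an alias table is given, protein identifiers are
#' mapped to symbols with [map_ppi_aliases()].
#'
#' @param path link file path.
#' @param alias_path optional two-column TSV (`protein_id`, `symbol`).
#' @return edge data.frame (`gene_a`, `gene_b`, `combined_score`).
#' @export
read_ppi_links <- function(path, alias_path = NULL) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (all(c("protein1", "protein2") %in% names(df))) {
    names(df)[match(c("protein1", "protein2"), names(df))] <-
      c("gene_a", "gene_b")
  }
  miss <- setdiff(c("gene_a", "gene_b", "combined_score"), names(df))
  if (length(miss)) {
    stop(basename(path), " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!is.null(alias_path)) {
    aliases <- read_table_checked(alias_path, c("protein_id", "symbol"))
    df <- map_ppi_aliases(df, aliases)
  }
  check_ppi_edges(df)
}

#' Read a drug-gene interaction CSV
#'
#' Comma-separated with columns `drug_id`, `drug_name`, `gene_symbol` (or
#' `gene`) and optionally `action`.
#'
#' @param path CSV path.
#' @return interaction data.frame (`drug_id`, `drug_name`, `gene`,
#'   `action`).
#' @export
read_drug_interactions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"gene" %in% names(df) && "gene_symbol" %in% names(df)) {
    df$gene <- df$gene_symbol
  }
  miss <- setdiff(c("drug_id", "drug_name", "gene"), names(df))
  if (length(miss)) {
    stop(basename(path), " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!"action" %in% names(df)) df$action <- NA_character_
  df[c("drug_id", "drug_name", "gene", "action")]
}

#' Read an abstract corpus (JSONL or CSV)
#'
#' JSONL: one object per line with fields `pmid`, `title`, `year`,
#' `abstract`. CSV: the same columns (case-insensitive `PMID`, `Title`,
#' `Year`, `Abstract` accepted).
#'
#' @param path corpus path (`.jsonl`/`.json` or `.csv`).
#' @return abstract data.frame.
#' @export
read_abstracts <- function(path) {
  if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(lines, function(l) {
      x <- jsonlite::fromJSON(l)
      data.frame(pmid = as.character(x$pmid),
                 title = as.character(x$title %||% ""),
                 year = x$year, abstract = as.character(x$abstract %||% ""),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    names(df) <- tolower(names(df))
    miss <- setdiff(c("pmid", "title", "year", "abstract"), names(df))
    if (length(miss)) {
      stop(basename(path), " is missing column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    df[c("pmid", "title", "year", "abstract")]
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a one-symbol-per-line gene lexicon
#' @param path text file path.
#' @return character vector of symbols.
#' @export
read_lexicon <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x)])
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a per-gene statistics table as TSV
#' @param stats data.frame (e.g. `analyze_cnv(...)$stats`).
#' @param path output TSV path.
#' @export
write_gene_stats <- function(stats, path) write_tsv(stats, path)

#' Write a risk-gene set as a gene list plus JSON sidecar
#'
#' Writes `<prefix>.txt` (one gene per line) and `<prefix>.json` recording
#' the selection parameters (alpha, cutoff method and value, stratum,
#' source).
#'
#' @param risk a `risk_gene_set` from [select_risk_genes()].
#' @param prefix output path prefix.
#' @export
write_risk_gene_set <- function(risk, prefix) {
  stopifnot(inherits(risk, "risk_gene_set"))
  writeLines(risk$genes, paste0(prefix, ".txt"))
  meta <- list(genes = risk$genes, alpha = risk$alpha,
               score_cutoff = risk$score_cutoff,
               selection_method = risk$selection_method,
               stratum = risk$stratum, source = risk$source)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' Write a neighbor map as TSV plus JSON
#' @param map a `neighbor_map` from [expand_neighbors()].
#' @param prefix output path prefix (`<prefix>.tsv`, `<prefix>.json`).
#' @export
write_neighbor_map <- function(map, prefix) {
  stopifnot(inherits(map, "neighbor_map"))
  write_tsv(map$edge_table, paste0(prefix, ".tsv"))
  jsonlite::write_json(list(cutoff = map$cutoff, strict = map$strict,
                            entries = map$entries),
                       paste0(prefix, ".json"), auto_unbox = TRUE)
  invisible(prefix)
}

#' Write an evidence table as TSV
#' @param evidence data.frame from [extract_targets()].
#' @param path output TSV path.
#' @export
write_evidence <- function(evidence, path) write_tsv(evidence, path)

#' Write the ranked drug enrichment table as TSV
#' @param enrichment result of [enrich_all()] (or its `results` element).
#' @param path output TSV path.
#' @export
write_drug_results <- function(enrichment, path) {
  df <- if (is.data.frame(enrichment)) enrichment else enrichment$results
  write_tsv(df, path)
}

#' Write the Sankey edge table as TSV
#' @param sankey data.frame from [report_summary()].
#' @param path output TSV path.
#' @export
write_sankey_edges <- function(sankey, path) write_tsv(sankey, path)
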