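#' @title Literature-based gene validation
#' @name literature_validation
#' @description
#' Cleans an abstract corpus (missing abstracts, pre-cutoff years, duplicate
#' PMIDs), extracts gene-evidence records through a pluggable extraction
#' backend, and validates candidate risk genes against the extracted
#' evidence. The shipped backend is a deterministic lexicon extractor:
#' whole-token, case-sensitive gene-symbol matching with simple sentence
#' segmentation. An LLM-based extractor can be plugged in as any function
#' with the same record-level contract.
NULL

#' Clean an abstract corpus
#'
#' Drops records with a missing or empty abstract, an unparseable publication
#' year, a year before `min_year`, or a duplicated PMID (first occurrence
#' kept), and reports per-reason drop counts.
#'
#' @param records data.frame with columns `pmid`, `title`, `year`,
#'   `abstract`.
#' @param min_year earliest retained publication year (default 2001, i.e.
#'   "after the year 2000").
#' @return the retained data.frame, with a `drop_counts` attribute (named
#'   integer vector: `missing_abstract`, `bad_year`, `old_year`,
#'   `duplicate_pmid`).
#' @export
clean_abstracts <- function(records, min_year = 2001) {
  need <- c("pmid", "title", "year", "abstract")
  if (!is.data.frame(records) || !all(need %in% names(records))) {
    stop("`records` must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  n0 <- nrow(records)
  abs_txt <- as.character(records$abstract)
  ok_abs <- !is.na(abs_txt) & trimws(abs_txt) != ""
  missing_abstract <- sum(!ok_abs)
  records <- records[ok_abs, , drop = FALSE]

  yr <- suppressWarnings(as.integer(as.character(records$year)))
  bad_year <- sum(is.na(yr))
  records <- records[!is.na(yr), , drop = FALSE]
  yr <- yr[!is.na(yr)]
  old_year <- sum(yr < min_year)
  records <- records[yr >= min_year, , drop = FALSE]

  dup <- duplicated(records$pmid)
  duplicate_pmid <- sum(dup)
  records <- records[!dup, , drop = FALSE]
  rownames(records) <- NULL
  attr(records, "drop_counts") <- c(
    missing_abstract = missing_abstract, bad_year = bad_year,
    old_year = old_year, duplicate_pmid = duplicate_pmid)
  records
}

# Sentence boundaries: [.!?] followed by whitespace and an upper-case or
# digit sentence opener, guarded against common abbreviations. Returned
# sentences are verbatim substrings of the input text.
split_sentences <- function(text) {
  if (is.na(text) || text == "") return(character(0))
  guard <- "(?<!\\be\\.g)(?<!\\bi\\.e)(?<!\\bet al)(?<!\\bvs)(?<!\\bFig)(?<!\\bDr)(?<!\\b[A-Z])"
  m <- gregexpr(paste0(guard, "[.!?](?=\\s+[A-Z0-9])"), text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(trimws(text))
  ends <- c(as.integer(m), nchar(text))
  starts <- c(1L, as.integer(m) + 1L)
  sent <- substring(text, starts, ends)
  sent <- trimws(sent)
  sent[nzchar(sent)]
}

#' Deterministic lexicon extraction backend
#'
#' Builds an extraction backend that scans each abstract sentence for
#' whole-token, case-sensitive matches against a gene-symbol lexicon (so
#' `EGFR` never matches inside `VEGFR`). If a drug lexicon is supplied, drug
#' names co-mentioned in the same sentence are recorded as annotation.
#'
#' @param gene_lexicon character vector of gene symbols to recognise.
#' @param drug_lexicon optional character vector of drug names.
#' @return a backend function `f(record)` returning a data.frame with
#'   columns `gene`, `sentence`, `drugs` for one abstract record; usable
#'   with [extract_targets()].
#' @export
lexicon_extractor <- function(gene_lexicon, drug_lexicon = character(0)) {
  gene_lexicon <- unique(as.character(gene_lexicon))
  token_re <- function(sym) {
    paste0("(?<![A-Za-z0-9_])", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", sym),
           "(?![A-Za-z0-9_])")
  }
  gene_res <- vapply(gene_lexicon, token_re, character(1))
  drug_res <- vapply(drug_lexicon, token_re, character(1))
  function(record) {
    sentences <- split_sentences(as.character(record$abstract))
    hits <- list()
    for (s in sentences) {
      g <- gene_lexicon[vapply(gene_res, grepl, logical(1), x = s, perl = TRUE)]
      if (!length(g)) next
      d <- if (length(drug_res)) {
        drug_lexicon[vapply(drug_res, grepl, logical(1), x = s, perl = TRUE)]
      } else character(0)
      hits[[length(hits) + 1L]] <- data.frame(
        gene = g, sentence = s, drugs = paste(d, collapse = ";"),
        stringsAsFactors = FALSE)
    }
    if (!length(hits)) {
      return(data.frame(gene = character(0), sentence = character(0),
                        drugs = character(0)))
    }
    do.call(rbind, hits)
  }
}

#' Extract gene-evidence records from a cleaned corpus
#'
#' Applies an extraction backend to every abstract and concatenates the
#' results into evidence records (PMID, gene, evidence sentence, co-mentioned
#' drugs). Backend output violating the evidence invariants -- the sentence
#' must be a verbatim substring of the abstract and must contain the gene as
#' a whole token -- is rejected and counted; a backend failing on more than
#' half the records aborts the run.
#'
#' @param records cleaned abstract data.frame (see [clean_abstracts()]).
#' @param extractor backend function `f(record)` as returned by
#'   [lexicon_extractor()].
#' @return data.frame with columns `pmid`, `gene`, `evidence_sentence`,
#'   `drugs`; rejected-record counts in the `rejected` attribute.
#' @export
extract_targets <- function(records, extractor) {
  if (!is.function(extractor)) stop("`extractor` must be a function", call. = FALSE)
  out <- vector("list", nrow(records))
  failures <- 0L
  rejected <- 0L
  for (i in seq_len(nrow(records))) {
    rec <- records[i, , drop = FALSE]
    res <- tryCatch(extractor(rec), error = function(e) NULL)
    if (is.null(res)) {
      failures <- failures + 1L
      next
    }
    if (!nrow(res)) next
    ok <- vapply(seq_len(nrow(res)), function(j) {
      grepl(res$sentence[j], rec$abstract, fixed = TRUE) &&
        grepl(paste0("(?<![A-Za-z0-9_])",
                     gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", res$gene[j]),
                     "(?![A-Za-z0-9_])"),
              res$sentence[j], perl = TRUE)
    }, logical(1))
    rejected <- rejected + sum(!ok)
    res <- res[ok, , drop = FALSE]
    if (nrow(res)) {
      out[[i]] <- data.frame(pmid = rec$pmid, gene = res$gene,
                             evidence_sentence = res$sentence,
                             drugs = res$drugs, stringsAsFactors = FALSE)
    }
  }
  if (nrow(records) > 0L && failures > nrow(records) / 2) {
    stop("extraction backend failed on more than half the records",
         call. = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  ev <- if (length(out)) do.call(rbind, out) else {
    data.frame(pmid = character(0), gene = character(0),
               evidence_sentence = character(0), drugs = character(0))
  }
  rownames(ev) <- NULL
  attr(ev, "rejected") <- c(invalid_records = rejected,
                            failed_abstracts = failures)
  ev
}

#' Validate candidate genes against literature evidence
#'
#' Retains candidates supported by at least `min_articles` distinct PMIDs in
#' the evidence table, and keeps the full per-gene support map for audit.
#'
#' @param candidates character vector of candidate gene symbols.
#' @param evidence evidence data.frame from [extract_targets()].
#' @param min_articles minimum number of distinct supporting articles
#'   (default 1).
#' @return object of class `validated_gene_set`: list with `genes`,
#'   `support` (named list gene -> PMID character vector, validated genes
#'   only) and `min_articles`.
#' @export
validate_genes <- function(candidates, evidence, min_articles = 1) {
  candidates <- unique(as.character(candidates))
  ev <- evidence[evidence$gene %in% candidates, , drop = FALSE]
  support <- lapply(split(as.character(ev$pmid), ev$gene), unique)
  n_support <- vapply(support, length, integer(1))
  keep <- names(support)[n_support >= min_articles]
  structure(list(genes = candidates[candidates %in% keep],
                 support = support[keep], min_articles = min_articles),
            class = "validated_gene_set")
}

#' @export
print.validated_gene_set <- function(x, ...) {
  cat("Validated gene set:", length(x$genes), "gene(s) with >=",
      x$min_articles, "supporting article(s)\n")
  if (length(x$genes)) {
    cat("  genes:", paste(utils::head(x$genes, 20), collapse = ", "),
        if (length(x$genes) > 20) "...", "\n")
  }
  invisible(x)
}
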