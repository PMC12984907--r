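#' Upper-tail binomial probability
#'
#' Computes `P(X >= x)` for `X ~ Binomial(n, p)`. This is the shared
#' significance primitive for copy-number event counts (with a genome-wide
#' background event rate) and for gene-level mutation burdens (with a
#' CDS-length-proportional success probability). The tail is evaluated through
#' the binomial survival function rather than naive term-by-term summation,
#' which stays accurate for cohort-scale `n`.
#'
#' @param x observed success count (non-negative integer; `x > n` is allowed
#'   and yields 0, the probability of an impossible event).
#' @param n number of trials (positive integer).
#' @param p per-trial success probability in `[0, 1]`.
#' @return `P(X >= x)`, a probability in `[0, 1]`.
#' @examples
#' binomial_tail_p(2, 10, 0.1)
#' @export
binomial_tail_p <- function(x, n, p) {
  if (length(x) != 1L || !is.finite(x) || x < 0 || x != floor(x)) {
    stop("`x` must be a single non-negative integer", call. = FALSE)
  }
  if (length(n) != 1L || !is.finite(n) || n < 1 || n != floor(n)) {
    stop("`n` must be a single positive integer", call. = FALSE)
  }
  if (length(p) != 1L || !is.finite(p) || p < 0 || p > 1) {
    stop("`p` must be a single probability in [0, 1]", call. = FALSE)
  }
  if (x == 0) return(1)
  if (x > n) return(0)
  stats::pbinom(x - 1, size = n, prob = p, lower.tail = FALSE)
}

#' Add-one empirical permutation p-value
#'
#' Given a permutation null of resampled statistics, returns
#' `(1 + #\{counts >= observed\}) / (N + 1)`, the add-one-smoothed exceedance
#' fraction. Ties count as exceedances, and the smoothing bounds the result
#' away from zero at `1 / (N + 1)` so downstream FDR correction never sees an
#' exact zero.
#'
#' @param observed observed statistic (single non-negative number).
#' @param counts numeric vector of null statistics, one per permutation.
#' @return empirical p-value in `[1 / (N + 1), 1]`.
#' @examples
#' empirical_p(3, c(0, 1, 2, 3, 4))
#' @export
empirical_p <- function(observed, counts) {
  if (length(observed) != 1L || !is.finite(observed) || observed < 0) {
    stop("`observed` must be a single non-negative number", call. = FALSE)
  }
  if (length(counts) == 0L || anyNA(counts)) {
    stop("`counts` must be a non-empty numeric vector without NAs", call. = FALSE)
  }
  (1 + sum(counts >= observed)) / (length(counts) + 1)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values in the original input order, delegating to
#' [stats::p.adjust()]. Input validation enforces probabilities and (when
#' labels are supplied) unique labels, so the result can be joined back onto
#' per-gene or per-drug tables safely.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @param labels optional character vector of unique identifiers, same length
#'   as `pvalues`; returned as names on the result.
#' @return numeric vector of q-values, same order (and names) as the input.
#' @examples
#' bh_fdr(c(0.005, 0.03, 0.04))
#' @export
bh_fdr <- function(pvalues, labels = NULL) {
  if (length(pvalues) == 0L) stop("`pvalues` must be non-empty", call. = FALSE)
  if (anyNA(pvalues) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("`pvalues` must lie in [0, 1] with no NAs", call. = FALSE)
  }
  if (!is.null(labels)) {
    if (length(labels) != length(pvalues)) {
      stop("`labels` must match `pvalues` in length", call. = FALSE)
    }
    if (anyDuplicated(labels)) stop("`labels` must be unique", call. = FALSE)
  }
  q <- stats::p.adjust(pvalues, method = "BH")
  if (!is.null(labels)) names(q) <- labels
  q
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= x)` for the overlap between a fixed target set of size `K` and a
#' uniformly drawn set of size `n` from a universe of `M` genes. Used for
#' drug-target enrichment against the risk-gene set, with the druggable-gene
#' universe as background.
#'
#' @param x observed overlap.
#' @param M universe size.
#' @param K target-set size (`K <= M`).
#' @param n drawn-set size (`n <= M`).
#' @return `P(X >= x)`.
#' @export
hypergeom_tail_p <- function(x, M, K, n) {
  for (v in list(x = x, M = M, K = K, n = n)) {
    if (length(v) != 1L || !is.finite(v) || v < 0 || v != floor(v)) {
      stop("hypergeometric arguments must be single non-negative integers",
           call. = FALSE)
    }
  }
  if (M < 1) stop("`M` must be positive", call. = FALSE)
  if (K > M || n > M) stop("`K` and `n` cannot exceed `M`", call. = FALSE)
  if (x == 0) return(1)
  if (x > min(K, n)) return(0)
  stats::phyper(x - 1, m = K, n = M - K, k = n, lower.tail = FALSE)
}
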