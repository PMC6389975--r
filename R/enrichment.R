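#' Build the enrichment background of valid genes
#'
#' The background ("valid genes") is the set of genes that are expressed
#' — FPKM strictly above `fpkm_floor` in at least one sample — and carry
#' at least one annotation term. The expected probability p0 of a term is
#' its frequency among valid genes: `count(term) / n_valid`.
#'
#' @param gene_terms named list mapping gene ID to a character vector of
#'   term IDs (as from [transfer_annotations()]).
#' @param em an `expression_matrix` covering the same genes.
#' @param fpkm_floor expression floor defining "expressed" (default 5).
#' @return An object of class `enrichment_background` with fields
#'   `valid_genes`, `per_term_counts`, `expected_probability`,
#'   `gene_terms` (restricted to valid genes) and `fpkm_floor`.
#' @export
build_background <- function(gene_terms, em, fpkm_floor = 5) {
  stopifnot(inherits(em, "expression_matrix"))
  annotated <- names(gene_terms)[lengths(gene_terms) > 0]
  expressed <- rownames(em$fpkm)[apply(em$fpkm > fpkm_floor, 1, any)]
  valid <- intersect(annotated, expressed)
  if (!length(valid))
    stopf("no valid genes: nothing is both annotated and above FPKM %g",
          fpkm_floor)
  gt <- gene_terms[valid]
  counts <- table(unlist(gt, use.names = FALSE))
  per_term <- stats::setNames(as.integer(counts), names(counts))
  structure(list(
    valid_genes = valid,
    per_term_counts = per_term,
    expected_probability = per_term / length(valid),
    gene_terms = gt,
    fpkm_floor = fpkm_floor), class = "enrichment_background")
}

#' @export
print.enrichment_background <- function(x, ...) {
  cat(sprintf("enrichment_background: %d valid genes, %d terms (FPKM > %g)\n",
              length(x$valid_genes), length(x$per_term_counts), x$fpkm_floor))
  invisible(x)
}

#' Cumulative binomial probability P(X <= k)
#'
#' Exact lower-tail probability for X ~ Binomial(n, p), the statistic the
#' enrichment test compares against its significance level: values near 0
#' indicate underrepresentation, values near 1 overrepresentation.
#'
#' @param k integer number of successes observed, 0 <= k <= n.
#' @param n integer number of trials.
#' @param p success probability in \[0, 1\].
#' @return P(X <= k).
#' @export
binomial_cdf <- function(k, n, p) {
  if (any(n < 0) || any(n != round(n))) stopf("n must be a non-negative integer")
  if (any(k < 0) || any(k > n) || any(k != round(k)))
    stopf("k must be an integer with 0 <= k <= n")
  if (any(p < 0) || any(p > 1)) stopf("p must lie in [0, 1]")
  stats::pbinom(k, n, p)
}

#' Upper-tail binomial probability P(X >= k)
#'
#' Computed as `1 - P(X <= k - 1)` through the stable CDF; P(X >= 0) = 1.
#'
#' @inheritParams binomial_cdf
#' @return P(X >= k).
#' @export
binomial_sf <- function(k, n, p) {
  if (any(k < 0) || any(k > n) || any(k != round(k)))
    stopf("k must be an integer with 0 <= k <= n")
  ifelse(k == 0, 1, stats::pbinom(k - 1, n, p, lower.tail = FALSE))
}

#' FDR-derived significance level (Benjamini-Hochberg critical value)
#'
#' Benjamini-Hochberg step-up on a family of p-values: sort ascending,
#' find the largest rank i with `p(i) <= (i/m) * q`, and return that
#' p-value as the significance level alpha. If no rank qualifies, alpha
#' is 0 (nothing is called). Tests with p-values at or below alpha are
#' exactly the BH discoveries at rate q.
#'
#' @param p_values numeric vector of p-values in \[0, 1\]; must be
#'   non-empty.
#' @param q target false-discovery rate in (0, 1), default 0.01.
#' @return The significance level alpha (a single number).
#' @export
fdr_significance_level <- function(p_values, q = 0.01) {
  if (!length(p_values)) stopf("p-value family is empty")
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    stopf("p-values must lie in [0, 1]")
  if (q <= 0 || q >= 1) stopf("q must lie in (0, 1)")
  m <- length(p_values)
  ps <- sort(p_values)
  ok <- which(ps <= seq_len(m) / m * q)
  if (!length(ok)) return(0)
  ps[max(ok)]
}

#' Cumulative-binomial over/under-representation test across SDEG sets
#'
#' For each SDEG set and each background term: the sample size n is the
#' number of the set's genes that are valid (expressed and annotated), the
#' number of observations k counts those carrying the term, and the
#' cumulative binomial probability P = P(X <= k) under Binomial(n, p0) is
#' computed with the term's background frequency p0. Both one-sided
#' p-values — P(X <= k) for underrepresentation and P(X >= k) for
#' overrepresentation — across every set and term of the annotation type
#' are pooled into a single family, from which one significance level
#' alpha is derived by Benjamini-Hochberg at rate `q`. A term is called
#' underrepresented when P < alpha and overrepresented when P > 1 - alpha.
#'
#' @param sdeg_sets list of `sdeg_set` objects (or named list of gene-ID
#'   character vectors).
#' @param gene_terms named list mapping gene ID to term IDs; must be the
#'   same annotation type as the background.
#' @param bg an `enrichment_background` from [build_background()].
#' @param q false-discovery rate used to derive alpha (default 0.01).
#' @return data.frame of class `enrichment_table` with columns
#'   `set_name`, `term`, `n`, `k`, `p0`, `cumulative_probability`, `call`
#'   and attribute `alpha` (also echoed in column `alpha_used`).
#' @export
enrich_sets <- function(sdeg_sets, gene_terms, bg, q = 0.01) {
  stopifnot(inherits(bg, "enrichment_background"))
  ids <- lapply(sdeg_sets, function(s)
    if (inherits(s, "sdeg_set")) s$gene_ids else as.character(s))
  nm <- names(sdeg_sets)
  if (is.null(nm) || any(!nzchar(nm)))
    nm <- vapply(sdeg_sets, function(s)
      if (inherits(s, "sdeg_set")) format(s) else NA_character_, character(1))
  terms <- names(bg$per_term_counts)
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    members <- intersect(ids[[i]], bg$valid_genes)
    n <- length(members)
    if (n == 0)
      warnf("SDEG set '%s' has no valid annotated genes; all calls not_significant",
            nm[i])
    k <- if (n == 0) {
      stats::setNames(integer(length(terms)), terms)
    } else {
      tt <- table(factor(unlist(bg$gene_terms[members], use.names = FALSE),
                         levels = terms))
      stats::setNames(as.integer(tt), terms)
    }
    rows[[i]] <- data.frame(
      set_name = nm[i], term = terms, n = n, k = k[terms],
      p0 = as.numeric(bg$expected_probability[terms]),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, rows)
  res$cumulative_probability <- binomial_cdf(res$k, res$n, res$p0)
  p_under <- res$cumulative_probability
  p_over <- binomial_sf(res$k, res$n, res$p0)
  alpha <- fdr_significance_level(c(p_under, p_over), q)
  res$call <- "not_significant"
  testable <- res$n > 0
  res$call[testable & res$cumulative_probability < alpha] <- "underrepresented"
  res$call[testable & res$cumulative_probability > 1 - alpha] <- "overrepresented"
  res$alpha_used <- alpha
  attr(res, "alpha") <- alpha
  class(res) <- c("enrichment_table", "data.frame")
  res
}

#' Write an enrichment table as TSV
#'
#' @param et an `enrichment_table` from [enrich_sets()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_enrichment <- function(et, path) {
  write_tsv(as.data.frame(et), path)
}
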