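#' Hypergeometric over-representation analysis
#'
#' Tests a query gene set against each annotation term with the one-sided
#' hypergeometric tail \eqn{p = P(X \ge k)} for
#' \eqn{X \sim \mathrm{Hypergeom}(N, K, n)}, where `N` is the background
#' size, `K` the term size in the background, `n` the query size in the
#' background and `k` the overlap. P-values are Benjamini-Hochberg adjusted
#' across all tested terms and records are sorted by `p`.
#'
#' @param query Character vector of gene symbols.
#' @param annotations Annotation tibble from [read_gmt()] (columns `term_id`,
#'   `term_name`, list-column `genes`).
#' @param background Optional background universe; defaults to the union of
#'   all annotation genes. The query is intersected with the background
#'   before testing.
#' @return A tibble with columns `term_id`, `term_name`, `k`, `K`, `n`, `N`,
#'   `p`, `p_adj`, sorted by `p`.
#' @export
hypergeom_enrich <- function(query, annotations, background = NULL) {
  query <- unique(norm_symbol(query))
  bg <- if (is.null(background)) {
    unique(unlist(annotations$genes))
  } else {
    unique(norm_symbol(background))
  }
  q <- intersect(query, bg)
  if (length(q) == 0) abort("query has no genes in the background universe")
  N <- length(bg)
  n <- length(q)
  res <- annotations %>%
    mutate(
      genes = purrr::map(genes, ~ intersect(.x, bg)),
      K = lengths(genes),
      k = purrr::map_int(genes, ~ length(intersect(.x, q))),
      n = n, N = N,
      p = phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    ) %>%
    filter(K > 0) %>%
    select(term_id, term_name, k, K, n, N, p)
  res$p_adj <- bh_adjust(res$p)
  arrange(res, p, term_id)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' the input order is preserved in the output.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric())
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Pathway-coverage statistic
#'
#' Fraction of the reference selection's significantly enriched terms that
#' are recovered by the query selection's enrichment — the statistic used to
#' check that an optimised component group retains the functional signal of
#' the full shared-gene (CAP) set.
#'
#' @param query_records,reference_records Enrichment tibbles from
#'   [hypergeom_enrich()] over the same annotation universe.
#' @param alpha Significance cutoff (default 0.05).
#' @param on Apply the cutoff to `"raw"` p-values (default, matching the
#'   common practice of thresholding unadjusted p at 0.05) or `"adjusted"`
#'   (recommended when term counts are large).
#' @return A one-row tibble of class `coverage_report` with `n_reference`,
#'   `n_query`, `n_shared`, `coverage_fraction` and list-columns of the term
#'   ids involved.
#' @export
pathway_coverage <- function(query_records, reference_records, alpha = 0.05,
                             on = c("raw", "adjusted")) {
  on <- match.arg(on)
  col <- if (on == "raw") "p" else "p_adj"
  qsig <- query_records$term_id[query_records[[col]] < alpha]
  rsig <- reference_records$term_id[reference_records[[col]] < alpha]
  if (length(rsig) == 0) {
    abort(paste0("no significant reference terms at alpha = ", alpha,
                 " (", on, " p); relax alpha or check the reference query"))
  }
  shared <- intersect(qsig, rsig)
  out <- tibble(
    n_reference = length(rsig),
    n_query = length(qsig),
    n_shared = length(shared),
    coverage_fraction = length(shared) / length(rsig),
    reference_terms = list(rsig),
    query_terms = list(qsig),
    shared_terms = list(shared)
  )
  class(out) <- c("coverage_report", class(out))
  out
}
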