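# Gene-set enrichment of interactome subsets with an explicit custom
# background: upper-tail hypergeometric tests with Benjamini-Hochberg
# control. Typical use is testing one bait's interactome against all PPIs
# identified in the dataset.

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of drawing at
#' least `k` annotated genes when `n` genes are drawn without replacement
#' from a background of `N` genes of which `K` carry the annotation.
#'
#' @param k Observed overlap.
#' @param n Query size.
#' @param K Annotated genes in the background.
#' @param N Background size.
#' @return The p-value in (0, 1].
#' @export
#' @examples
#' hypergeom_upper_tail(2, 2, 2, 4) # 1/6
hypergeom_upper_tail <- function(k, n, K, N) {
  ok <- k >= 0 & n >= 0 & K >= 0 & k <= pmin(n, K) & n <= N & K <= N
  if (any(!ok)) {
    abort("Need 0 <= k <= min(n, K) and n, K <= N",
          class = "tfdistill_validation_error")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; output order matches input.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, element-wise >= the raw values.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p) | p <= 0 | p > 1)) {
    abort("p-values must lie in (0, 1]", class = "tfdistill_validation_error")
  }
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric gene-set enrichment with a custom background
#'
#' Tests each gene set for over-representation in `query` relative to
#' `background`. Set membership is intersected with the background before
#' testing, so all counts are conditioned on the chosen universe; query
#' genes outside the background are dropped with a warning.
#'
#' @param query Character vector of genes of interest (e.g. one TF's preys).
#' @param background Character vector, the gene universe (e.g. every prey
#'   identified in the study).
#' @param gene_sets Tibble `term_id`, `term_name`, `gene` ([read_gmt()]).
#' @return Tibble with one row per gene set having >= 1 background member:
#'   `term_id`, `term_name`, `k` (overlap), `n` (query size), `K` (set size
#'   in background), `N` (background size), `p_value`, `fdr`; sorted by
#'   `p_value`.
#' @export
enrich <- function(query, background, gene_sets) {
  query <- unique(query)
  background <- unique(background)
  outside <- setdiff(query, background)
  if (length(outside) > 0) {
    warn(paste0("Dropping ", length(outside),
                " query gene(s) outside the background"))
    query <- intersect(query, background)
  }
  sets <- gene_sets %>%
    dplyr::filter(.data$gene %in% background) %>%
    dplyr::distinct(.data$term_id, .data$term_name, .data$gene)
  if (nrow(sets) == 0) {
    return(tibble(term_id = character(), term_name = character(),
                  k = integer(), n = integer(), K = integer(), N = integer(),
                  p_value = numeric(), fdr = numeric()))
  }
  n <- length(query)
  N <- length(background)
  res <- sets %>%
    dplyr::group_by(.data$term_id, .data$term_name) %>%
    dplyr::summarise(
      k = sum(.data$gene %in% query),
      K = dplyr::n(),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      n = n, N = N,
      p_value = hypergeom_upper_tail(.data$k, n, .data$K, N)
    )
  res$fdr <- bh_fdr(res$p_value)
  res %>%
    dplyr::select("term_id", "term_name", "k", "n", "K", "N", "p_value",
                  "fdr") %>%
    dplyr::arrange(.data$p_value, .data$term_id)
}
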