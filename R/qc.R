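# Replicate-agreement quality control: Pearson correlation between the
# spectral-count vectors of replicate runs of the same bait and method.

#' Pearson correlation with explicit degenerate handling
#'
#' Thin, validating wrapper around the product-moment correlation. Constant
#' vectors make the correlation undefined; this errors rather than silently
#' returning 0 or NA.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @param log_transform If `TRUE`, apply `log1p()` to both vectors first
#'   (spectral counts are skewed; the raw scale is the default).
#' @return The correlation coefficient, a single number in \[-1, 1\].
#' @export
#' @examples
#' pearson_r(c(1, 2, 3), c(1, 2, 4))
pearson_r <- function(x, y, log_transform = FALSE) {
  if (length(x) != length(y)) {
    abort("Vectors must have equal length", class = "tfdistill_validation_error")
  }
  if (length(x) < 2) {
    abort("Need at least 2 observations", class = "tfdistill_validation_error")
  }
  if (log_transform) {
    x <- log1p(x)
    y <- log1p(y)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("Correlation undefined for a constant vector",
          class = "tfdistill_validation_error")
  }
  stats::cor(x, y, method = "pearson")
}

#' Replicate-pair correlation report
#'
#' For each bait and method, computes the Pearson correlation between every
#' unordered pair of replicate runs. Vectors span the union of preys seen in
#' either run, with zero substituted where a prey is absent: in count data,
#' absence is informative. Baits with a single run yield no pairs.
#'
#' @param runs Run tibble ([read_runs()] layout).
#' @param log_transform Passed to [pearson_r()].
#' @return Tibble with columns `bait`, `method`, `rep_a`, `rep_b`
#'   (labels `"bio<k>.tech<j>"`), `r`, `n_preys` (union size).
#' @export
replicate_report <- function(runs, log_transform = FALSE) {
  empty <- tibble(bait = character(), method = character(),
                  rep_a = character(), rep_b = character(),
                  r = numeric(), n_preys = integer())
  if (nrow(runs) == 0) return(empty)
  runs <- runs %>%
    dplyr::mutate(rep = paste0("bio", .data$bio_rep, ".tech", .data$tech_rep))
  groups <- runs %>% dplyr::distinct(.data$bait, .data$method)
  purrr::pmap_dfr(groups, function(bait, method) {
    sub <- runs[runs$bait == bait & runs$method == method, ]
    reps <- sort(unique(sub$rep))
    if (length(reps) < 2) return(empty)
    wide <- sub %>%
      dplyr::select("rep", "prey", "spectral_count") %>%
      tidyr::pivot_wider(names_from = "rep", values_from = "spectral_count",
                         values_fill = 0)
    combos <- utils::combn(reps, 2)
    purrr::map_dfr(seq_len(ncol(combos)), function(i) {
      a <- combos[1, i]
      b <- combos[2, i]
      tibble(
        bait = bait, method = method, rep_a = a, rep_b = b,
        r = pearson_r(wide[[a]], wide[[b]], log_transform = log_transform),
        n_preys = nrow(wide)
      )
    })
  })
}
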