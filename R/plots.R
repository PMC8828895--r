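# ggplot2 views of the main result types. These are quick-look diagnostics;
# publication figures are out of scope.

#' Plot filter-decision composition
#'
#' Bar chart of how many scored interactions each cascade rule claimed,
#' split by method.
#'
#' @param object A `tf_distilled` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tf_distilled <- function(object, ...) {
  d <- object$decisions
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rule, fill = .data$method)) +
    ggplot2::geom_bar(position = "dodge") +
    ggplot2::labs(x = "filter rule", y = "interactions",
                  title = "Confidence-cascade decisions") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot method overlap
#'
#' @param bioid,apms Distilled interaction tibbles.
#' @return A ggplot bar chart of BioID-only / shared / AP-MS-only pair
#'   counts.
#' @export
plot_method_overlap <- function(bioid, apms) {
  counts <- method_overlap_counts(bioid, apms)
  d <- tibble(
    set = factor(c("BioID only", "both", "AP-MS only"),
                 levels = c("BioID only", "both", "AP-MS only")),
    n = c(counts$n_bioid_only, counts$n_both, counts$n_apms_only)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$set, y = .data$n)) +
    ggplot2::geom_col(fill = c("#4477AA", "#44AA77", "#AA4444")) +
    ggplot2::labs(x = NULL, y = "unique bait-prey pairs",
                  title = "Method overlap") +
    ggplot2::theme_minimal()
}

#' Plot replicate-correlation distribution
#'
#' @param report Tibble from [replicate_report()].
#' @return A ggplot dot plot of Pearson r per bait.
#' @export
plot_replicate_correlation <- function(report) {
  ggplot2::ggplot(report, ggplot2::aes(x = .data$bait, y = .data$r,
                                       colour = .data$method)) +
    ggplot2::geom_point() +
    ggplot2::ylim(-1, 1) +
    ggplot2::labs(x = "bait", y = "replicate Pearson r",
                  title = "Replicate agreement") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot a prey-prey correlation matrix
#'
#' Heat map of the correlation structure, rows and columns in the order
#' given (pass a matrix reordered by a dendrogram for the clustered view).
#'
#' @param cormat Correlation matrix from [prey_correlation_matrix()].
#' @return A ggplot tile plot.
#' @export
plot_prey_correlation <- function(cormat) {
  d <- as_tibble(as.table(cormat), .name_repair = ~ c("prey_a", "prey_b", "r"))
  d$prey_a <- factor(d$prey_a, levels = rownames(cormat))
  d$prey_b <- factor(d$prey_b, levels = colnames(cormat))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$prey_a, y = .data$prey_b,
                                  fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r",
                  title = "Prey-prey correlation") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
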