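# broom-style accessors for the package's result objects.

#' Tidy a distilled interactome
#'
#' @param x A `tf_distilled` object from [distill_interactome()].
#' @param what `"interactions"` (the surviving edges, default) or
#'   `"decisions"` (every scored edge with its filter rule).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.tf_distilled <- function(x, what = c("interactions", "decisions"), ...) {
  what <- match.arg(what)
  as_tibble(x[[what]])
}

#' One-row summary of a distilled interactome
#'
#' @param x A `tf_distilled` object.
#' @param ... Unused.
#' @return One-row tibble: `n_input`, `n_kept`, `n_saint_fail`,
#'   `n_crapome_fail`, `saint_cutoff`.
#' @export
glance.tf_distilled <- function(x, ...) {
  rules <- x$decisions$rule
  tibble(
    n_input = length(rules),
    n_kept = sum(rules == "pass"),
    n_saint_fail = sum(rules == "saint_fail"),
    n_crapome_fail = sum(!rules %in% c("pass", "saint_fail")),
    saint_cutoff = x$thresholds$saint_cutoff
  )
}

#' Tidy a flat prey clustering
#'
#' @param x A `prey_clusters` object from [extract_clusters()].
#' @param ... Unused.
#' @return Tibble `cluster`, `member` (leaf order).
#' @export
tidy.prey_clusters <- function(x, ...) {
  tibble(cluster = x$cluster, member = x$member)
}

#' One-row summary of a flat prey clustering
#'
#' @param x A `prey_clusters` object.
#' @param ... Unused.
#' @return One-row tibble: `k`, `n_members`, `largest_cluster`,
#'   `largest_size`.
#' @export
glance.prey_clusters <- function(x, ...) {
  sizes <- table(x$cluster)
  top <- which.max(sizes)
  tibble(
    k = length(sizes),
    n_members = length(x$member),
    largest_cluster = names(sizes)[top],
    largest_size = as.integer(sizes[top])
  )
}
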