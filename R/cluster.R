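# Bait-by-prey hierarchical clustering and prey-prey correlation clustering
# with driving-bait attribution. Clustering itself is standard agglomerative
# (stats::hclust); the package's job is building the right matrices, the
# correlation metric, deterministic labeling, and the driving-bait ranking.

#' Build the bait-by-prey abundance matrix
#'
#' Rows are baits, columns are preys, values are average spectral counts of
#' the high-confidence interactions; pairs that did not survive filtering
#' are zero.
#'
#' @param interactions Distilled interaction tibble (`bait`, `prey`,
#'   `avg_spec`).
#' @return A numeric matrix with bait rownames and prey colnames (0 x 0 for
#'   an empty table). Row and column order is alphabetical for determinism.
#' @export
build_bait_prey_matrix <- function(interactions) {
  if (nrow(interactions) == 0) {
    return(matrix(numeric(0), nrow = 0, ncol = 0))
  }
  baits <- sort(unique(interactions$bait))
  preys <- sort(unique(interactions$prey))
  m <- matrix(0, nrow = length(baits), ncol = length(preys),
              dimnames = list(baits, preys))
  m[cbind(interactions$bait, interactions$prey)] <- interactions$avg_spec
  m
}

#' Hierarchical clustering of a bait-by-prey matrix
#'
#' Deterministic agglomerative clustering of either axis, with Euclidean
#' distance (default) or a correlation distance (1 - Pearson) and average
#' (default) or complete linkage.
#'
#' @param mat Bait-by-prey matrix ([build_bait_prey_matrix()]).
#' @param axis Cluster `"bait"` rows or `"prey"` columns.
#' @param metric `"euclidean"` or `"pearson"` (distance 1 - r).
#' @param linkage `"average"` or `"complete"`.
#' @return An object of class [stats::hclust].
#' @export
hierarchical_cluster <- function(mat, axis = c("bait", "prey"),
                                 metric = c("euclidean", "pearson"),
                                 linkage = c("average", "complete")) {
  axis <- match.arg(axis)
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  x <- if (axis == "bait") mat else t(mat)
  if (nrow(x) < 2) {
    abort("Need at least 2 items on the clustered axis",
          class = "tfdistill_validation_error")
  }
  d <- if (metric == "euclidean") {
    stats::dist(x, method = "euclidean")
  } else {
    stats::as.dist(1 - stats::cor(t(x)))
  }
  stats::hclust(d, method = linkage)
}

#' Prey-prey Pearson correlation matrix
#'
#' Correlates prey abundance profiles across baits. Preys with a constant
#' profile (usually all-equal counts from a single bait) have no defined
#' correlation; they are dropped with a warning and recorded in the
#' `"excluded"` attribute of the result.
#'
#' @param mat Bait-by-prey matrix; needs >= 2 baits.
#' @return A symmetric prey-by-prey correlation matrix with unit diagonal;
#'   attribute `excluded` lists dropped constant-profile preys.
#' @export
prey_correlation_matrix <- function(mat) {
  if (nrow(mat) < 2) {
    abort("Need >= 2 baits to correlate prey profiles",
          class = "tfdistill_validation_error")
  }
  sds <- apply(mat, 2, stats::sd)
  constant <- colnames(mat)[sds == 0]
  if (length(constant) > 0) {
    warn(paste0("Dropping ", length(constant),
                " constant-profile prey(s) from correlation"))
    mat <- mat[, sds > 0, drop = FALSE]
  }
  cc <- stats::cor(mat)
  attr(cc, "excluded") <- constant
  cc
}

# letters, then AA, AB, ... for more than 26 clusters
cluster_letters <- function(k) {
  if (k <= 26) return(LETTERS[seq_len(k)])
  extra <- k - 26
  c(LETTERS, paste0(rep(LETTERS, each = 26), LETTERS)[seq_len(extra)])
}

#' Cut a dendrogram into labeled flat clusters
#'
#' Cuts an [stats::hclust] tree at `k` groups or at height `h` and labels
#' the clusters A, B, C, ... in dendrogram leaf order (figure-style
#' lettering; letters are an ordering device, not portable identities).
#'
#' @param hc An `hclust` object (e.g. from [hierarchical_cluster()] on the
#'   prey axis, or from clustering a [prey_correlation_matrix()]).
#' @param k Number of clusters (exclusive with `h`).
#' @param h Cut height.
#' @return An object of class `prey_clusters`: a tibble `cluster`, `member`
#'   ordered by leaf order, with the `hclust` object kept in attribute
#'   `"hclust"`.
#' @export
extract_clusters <- function(hc, k = NULL, h = NULL) {
  if (is.null(k) == is.null(h)) {
    abort("Supply exactly one of k or h", class = "tfdistill_validation_error")
  }
  cut <- if (!is.null(k)) stats::cutree(hc, k = k) else stats::cutree(hc, h = h)
  leaf_order <- hc$labels[hc$order]
  cut <- cut[leaf_order]
  first_seen <- unique(unname(cut))
  letter_of <- stats::setNames(cluster_letters(length(first_seen)),
                               as.character(first_seen))
  out <- tibble(
    cluster = unname(letter_of[as.character(cut)]),
    member = names(cut)
  )
  structure(out, class = c("prey_clusters", class(out)), hclust = hc)
}

#' Rank baits driving a prey cluster
#'
#' For one cluster (or every cluster of a `prey_clusters` object), counts
#' how many cluster members each bait interacts with in the distilled
#' table. Sorted by descending count; ties broken alphabetically. Baits
#' touching no member are omitted unless `keep_zero = TRUE`.
#'
#' @param clusters A `prey_clusters` object, or a character vector of prey
#'   members (one cluster).
#' @param interactions Distilled interaction tibble (`bait`, `prey`).
#' @param keep_zero Keep baits with zero cluster members (listed last).
#' @return Tibble `cluster` (absent when a bare member vector was given),
#'   `bait`, `n_members`.
#' @export
driving_baits <- function(clusters, interactions, keep_zero = FALSE) {
  rank_one <- function(members) {
    counts <- interactions %>%
      dplyr::distinct(.data$bait, .data$prey) %>%
      dplyr::filter(.data$prey %in% members) %>%
      dplyr::count(.data$bait, name = "n_members")
    if (keep_zero) {
      counts <- tibble(bait = sort(unique(interactions$bait))) %>%
        dplyr::left_join(counts, by = "bait") %>%
        dplyr::mutate(n_members = dplyr::coalesce(.data$n_members, 0L))
    }
    dplyr::arrange(counts, dplyr::desc(.data$n_members), .data$bait)
  }
  if (inherits(clusters, "prey_clusters")) {
    ids <- unique(clusters$cluster)
    purrr::map_dfr(ids, function(id) {
      rank_one(clusters$member[clusters$cluster == id]) %>%
        dplyr::mutate(cluster = id, .before = 1)
    })
  } else {
    rank_one(clusters)
  }
}
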