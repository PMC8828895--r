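# Network-level summaries of the distilled interactome: method overlap,
# known/novel fractions, prey degree, localization, bait-bait (TF-TF) edges,
# bidirectional pairs, the NFI partition, and complex-subunit coverage.
#
# Edge identity for overlap and reference comparisons is the undirected gene
# pair with methods collapsed; the directed bait -> prey orientation is kept
# on the network itself because it records who was the tagged bait.

#' Build the combined interactome network
#'
#' Merges per-method distilled interaction tables into one directed
#' bait -> prey edge table with provenance: `BioID`, `AP-MS`, or `both` when
#' the pair appears in both tables.
#'
#' @param bioid,apms Distilled interaction tibbles (columns `bait`, `prey`,
#'   and optionally `avg_spec`); either may be empty.
#' @return Tibble with columns `bait`, `prey`, `provenance`, and per-method
#'   average spectral counts `avg_spec_bioid`, `avg_spec_apms` (NA where the
#'   method did not detect the pair).
#' @export
build_network <- function(bioid, apms) {
  b <- pick_edge_cols(bioid) %>% dplyr::mutate(in_bioid = TRUE)
  a <- pick_edge_cols(apms) %>% dplyr::mutate(in_apms = TRUE)
  dplyr::full_join(
    dplyr::rename(b, avg_spec_bioid = "avg_spec"),
    dplyr::rename(a, avg_spec_apms = "avg_spec"),
    by = c("bait", "prey")
  ) %>%
    dplyr::mutate(
      in_bioid = dplyr::coalesce(.data$in_bioid, FALSE),
      in_apms = dplyr::coalesce(.data$in_apms, FALSE),
      provenance = dplyr::case_when(
        .data$in_bioid & .data$in_apms ~ "both",
        .data$in_bioid ~ "BioID",
        TRUE ~ "AP-MS"
      )
    ) %>%
    dplyr::select("bait", "prey", "provenance", "avg_spec_bioid",
                  "avg_spec_apms")
}

pick_edge_cols <- function(tbl) {
  if (nrow(tbl) == 0) {
    return(tibble(bait = character(), prey = character(), avg_spec = numeric()))
  }
  if (!"avg_spec" %in% names(tbl)) tbl$avg_spec <- NA_real_
  tbl %>%
    dplyr::select("bait", "prey", "avg_spec") %>%
    dplyr::distinct(.data$bait, .data$prey, .keep_all = TRUE)
}

#' Method-overlap counts
#'
#' Counts unique (bait, prey) pairs detected only by BioID, only by AP-MS,
#' or by both methods. The BioID-only count plus the shared count equals the
#' number of unique BioID pairs.
#'
#' @param bioid,apms Distilled interaction tibbles.
#' @return One-row tibble with `n_bioid_only`, `n_apms_only`, `n_both`.
#' @export
method_overlap_counts <- function(bioid, apms) {
  bp <- unique(paste(bioid$bait, bioid$prey, sep = "\r"))
  ap <- unique(paste(apms$bait, apms$prey, sep = "\r"))
  tibble(
    n_bioid_only = length(setdiff(bp, ap)),
    n_apms_only = length(setdiff(ap, bp)),
    n_both = length(intersect(bp, ap))
  )
}

#' Flag known interactions against reference edge sets
#'
#' An edge is "known" when its undirected gene pair occurs in at least one
#' of the supplied reference edge lists (direction-insensitive, methods
#' collapsed).
#'
#' @param network Network tibble from [build_network()].
#' @param references A list of normalized undirected pair tibbles
#'   ([read_edge_list()] layout); may be named.
#' @return The network with a logical `known` column added.
#' @export
annotate_known <- function(network, references) {
  if (length(references) == 0) {
    warn("No reference sets supplied; all edges flagged novel")
    return(dplyr::mutate(network, known = FALSE))
  }
  ref <- normalize_pairs(dplyr::bind_rows(references))
  key <- paste(ref$gene_a, ref$gene_b, sep = "\r")
  network %>%
    dplyr::mutate(
      known = paste(pmin(.data$bait, .data$prey),
                    pmax(.data$bait, .data$prey), sep = "\r") %in% key
    )
}

#' Known-interaction fractions per method
#'
#' @param network Network tibble with a `known` column ([annotate_known()]).
#' @return Tibble with one row per method: `method`, `n_edges`, `n_known`,
#'   `fraction_known`. An edge with provenance `both` counts toward both
#'   methods, matching how per-method totals are reported.
#' @export
known_fractions <- function(network) {
  purrr::map_dfr(c("BioID", "AP-MS"), function(m) {
    sub <- network[network$provenance %in% c(m, "both"), ]
    tibble(
      method = m,
      n_edges = nrow(sub),
      n_known = sum(sub$known),
      fraction_known = if (nrow(sub) == 0) NA_real_ else mean(sub$known)
    )
  })
}

#' Prey degree: number of distinct baits per prey
#'
#' Methods are collapsed: a prey seen with the same bait by both methods
#' counts that bait once.
#'
#' @param network Network tibble.
#' @return Tibble `prey`, `n_baits`, sorted by decreasing degree then prey.
#' @export
prey_degree <- function(network) {
  network %>%
    dplyr::distinct(.data$bait, .data$prey) %>%
    dplyr::count(.data$prey, name = "n_baits") %>%
    dplyr::arrange(dplyr::desc(.data$n_baits), .data$prey)
}

#' Fraction of annotated preys with nuclear localization
#'
#' A prey counts as nuclear when any of its compartment tags matches the
#' nuclear pattern (multi-localized proteins count as nuclear). The
#' denominator is the set of preys with at least one annotation;
#' unannotated preys are reported separately, never silently folded in.
#'
#' @param network Network tibble.
#' @param localization Tibble `prey`, `compartment` ([read_localization()]).
#' @param nuclear_pattern Regular expression (case-insensitive) defining
#'   nuclear compartments.
#' @return One-row tibble: `n_preys`, `n_annotated`, `n_unannotated`,
#'   `n_nuclear`, `fraction_nuclear` (NA when nothing is annotated).
#' @export
localization_fraction <- function(network, localization,
                                  nuclear_pattern = "nucle") {
  preys <- unique(network$prey)
  ann <- localization[localization$prey %in% preys, ]
  annotated <- unique(ann$prey)
  nuclear <- unique(ann$prey[grepl(nuclear_pattern, ann$compartment,
                                   ignore.case = TRUE)])
  tibble(
    n_preys = length(preys),
    n_annotated = length(annotated),
    n_unannotated = length(preys) - length(annotated),
    n_nuclear = length(nuclear),
    fraction_nuclear = if (length(annotated) == 0) NA_real_ else
      length(nuclear) / length(annotated)
  )
}

#' Bait-bait (TF-TF) edges
#'
#' Edges whose prey is itself a registered bait. Self-detections (a bait
#' finding itself) are excluded: these are interactions with *other* studied
#' baits.
#'
#' @param network Network tibble.
#' @param baits Character vector of registered bait identifiers.
#' @return The subset of network rows with `prey` in `baits` and
#'   `prey != bait`.
#' @export
bait_bait_edges <- function(network, baits) {
  network %>%
    dplyr::filter(.data$prey %in% baits, .data$prey != .data$bait)
}

#' Bidirectional bait pairs
#'
#' Unordered bait pairs connected by edges in both directions (each partner
#' detected the other when used as bait), with the provenance supporting
#' each direction.
#'
#' @param bb_edges Bait-bait edge tibble ([bait_bait_edges()]).
#' @return Tibble `gene_a`, `gene_b` (`gene_a < gene_b`), `provenance_ab`
#'   (edge gene_a -> gene_b), `provenance_ba`.
#' @export
bidirectional_pairs <- function(bb_edges) {
  if (nrow(bb_edges) == 0) {
    return(tibble(gene_a = character(), gene_b = character(),
                  provenance_ab = character(), provenance_ba = character()))
  }
  edges <- dplyr::distinct(bb_edges, .data$bait, .data$prey,
                           .keep_all = TRUE)
  fwd <- paste(edges$bait, edges$prey, sep = "\r")
  rev <- paste(edges$prey, edges$bait, sep = "\r")
  hit <- edges[fwd %in% rev & edges$bait < edges$prey, ]
  if (nrow(hit) == 0) {
    return(tibble(gene_a = character(), gene_b = character(),
                  provenance_ab = character(), provenance_ba = character()))
  }
  prov <- stats::setNames(edges$provenance, fwd)
  tibble(
    gene_a = hit$bait,
    gene_b = hit$prey,
    provenance_ab = unname(prov[paste(hit$bait, hit$prey, sep = "\r")]),
    provenance_ba = unname(prov[paste(hit$prey, hit$bait, sep = "\r")])
  )
}

#' Partition baits by their NFI connectivity
#'
#' Classifies every registered non-NFI bait by its bait-bait edges with the
#' nuclear factor 1 family: `to` (edges toward NFIs only), `from` (NFIs
#' detected it only), `both`, or `none`, and lists which NFIs it touches.
#'
#' @param bb_edges Bait-bait edge tibble.
#' @param baits Character vector of all registered baits.
#' @param nfi Character vector naming the NFI family baits.
#' @param direction Which edges count as "touching" an NFI for the `nfis`
#'   membership column: `"either"` (default), `"to"`, or `"from"`.
#' @return Tibble `bait`, `nfis` (comma-separated, "" when none),
#'   `n_nfis`, `class`.
#' @export
nfi_partition <- function(bb_edges, baits,
                          nfi = c("NFIA", "NFIB", "NFIC", "NFIX"),
                          direction = c("either", "to", "from")) {
  direction <- match.arg(direction)
  others <- sort(setdiff(unique(baits), nfi))
  purrr::map_dfr(others, function(tf) {
    to <- sort(unique(bb_edges$prey[bb_edges$bait == tf &
                                      bb_edges$prey %in% nfi]))
    from <- sort(unique(bb_edges$bait[bb_edges$prey == tf &
                                        bb_edges$bait %in% nfi]))
    touched <- switch(direction,
                      either = union(to, from),
                      to = to,
                      from = from)
    cls <- if (length(to) > 0 && length(from) > 0) "both"
           else if (length(to) > 0) "to"
           else if (length(from) > 0) "from"
           else "none"
    tibble(bait = tf, nfis = paste(sort(touched), collapse = ","),
           n_nfis = length(touched), class = cls)
  })
}

#' Per-NFI interactor counts
#'
#' How many non-NFI baits touch each NFI family member (either direction by
#' default).
#'
#' @inheritParams nfi_partition
#' @return Tibble `nfi`, `n_tfs`.
#' @export
nfi_counts <- function(bb_edges, baits,
                       nfi = c("NFIA", "NFIB", "NFIC", "NFIX"),
                       direction = c("either", "to", "from")) {
  direction <- match.arg(direction)
  part <- nfi_partition(bb_edges, baits, nfi, direction)
  purrr::map_dfr(nfi, function(n) {
    tibble(nfi = n,
           n_tfs = sum(vapply(strsplit(part$nfis, ",", fixed = TRUE),
                              function(s) n %in% s, logical(1))))
  })
}

#' Complex-subunit coverage per bait
#'
#' For each bait and protein complex, the number of distinct complex
#' subunits among the bait's preys. The denominator is the number of the
#' complex's subunits identified anywhere in the network's prey set, i.e.
#' coverage is conditioned on what the dataset could see at all.
#'
#' @param network Network tibble.
#' @param complexes Tibble `complex_name`, `subunit` ([read_complexes()]).
#' @return Tibble `bait`, `complex_name`, `n_subunits_interacting`,
#'   `n_subunits_identified`, `coverage` (NA when no subunit of the complex
#'   was identified in the data).
#' @export
complex_coverage <- function(network, complexes) {
  all_preys <- unique(network$prey)
  identified <- complexes %>%
    dplyr::filter(.data$subunit %in% all_preys) %>%
    dplyr::count(.data$complex_name, name = "n_subunits_identified")
  denom <- complexes %>%
    dplyr::distinct(.data$complex_name) %>%
    dplyr::left_join(identified, by = "complex_name") %>%
    dplyr::mutate(n_subunits_identified =
                    dplyr::coalesce(.data$n_subunits_identified, 0L))
  tidyr::expand_grid(bait = sort(unique(network$bait)),
                     complex_name = denom$complex_name) %>%
    dplyr::left_join(denom, by = "complex_name") %>%
    dplyr::rowwise() %>%
    dplyr::mutate(
      n_subunits_interacting = length(intersect(
        complexes$subunit[complexes$complex_name == .data$complex_name],
        network$prey[network$bait == .data$bait]
      ))
    ) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(
      coverage = dplyr::if_else(.data$n_subunits_identified > 0,
                                .data$n_subunits_interacting /
                                  .data$n_subunits_identified,
                                NA_real_)
    ) %>%
    dplyr::select("bait", "complex_name", "n_subunits_interacting",
                  "n_subunits_identified", "coverage")
}
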