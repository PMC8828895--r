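# End-to-end orchestration: score -> distill (per method) -> QC -> network
# summaries -> clustering -> enrichment, with every table written to an
# output directory and the headline counts collected in one summary JSON.

as_input <- function(x, reader) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1) return(reader(x))
  x
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("Pipeline stage '", name, "' failed: ", conditionMessage(e)),
          class = "tfdistill_pipeline_error", parent = e)
  })
}

#' Run the full interactome pipeline
#'
#' Orchestrates the whole analysis over in-memory tibbles or file paths:
#' interaction scoring (supplied SAINT output, or the surrogate scorer from
#' runs + controls), the confidence cascade per method, replicate QC,
#' network summaries, optional prey clustering and per-bait enrichment.
#' All result tables are written as TSV into `out_dir` together with a
#' `summary.json` of the headline counts.
#'
#' @param out_dir Output directory (created if missing).
#' @param runs Run tibble or path ([read_runs()]).
#' @param controls Optional control runs or path; required when `scored` is
#'   not supplied.
#' @param scored Optional pre-scored interactions (tibble or SAINT-list
#'   path); when absent, [surrogate_score()] is used.
#' @param crapome Optional contaminant profile or path.
#' @param baits Optional character vector (or single-column file) of
#'   registered baits for the bait-bait analyses; defaults to the baits
#'   present in the runs.
#' @param references Optional list of reference edge tibbles or paths.
#' @param localization Optional localization tibble or path.
#' @param complexes Optional complex-definition tibble or path.
#' @param gene_sets Optional gene sets (tibble or GMT path) for per-bait
#'   enrichment against the all-interactome background.
#' @param thresholds A [filter_thresholds()] object.
#' @param cluster_k Optional number of prey clusters to extract (skipped
#'   when NULL or fewer than `cluster_k` preys survive).
#' @return Invisibly, the summary list (also written to
#'   `out_dir/summary.json`).
#' @export
run_pipeline <- function(out_dir, runs, controls = NULL, scored = NULL,
                         crapome = NULL, baits = NULL, references = NULL,
                         localization = NULL, complexes = NULL,
                         gene_sets = NULL,
                         thresholds = filter_thresholds(),
                         cluster_k = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  runs <- stage("read_runs", as_input(runs, read_runs))
  controls <- stage("read_controls", as_input(controls, read_control_runs))
  crapome <- stage("read_crapome", as_input(crapome, read_crapome))
  localization <- stage("read_localization",
                        as_input(localization, read_localization))
  complexes <- stage("read_complexes", as_input(complexes, read_complexes))
  gene_sets <- stage("read_gene_sets", as_input(gene_sets, read_gmt))
  if (!is.null(references)) {
    references <- stage("read_references",
                        lapply(references, as_input, reader = read_edge_list))
  }
  if (is.character(baits) && length(baits) == 1 && file.exists(baits)) {
    baits <- readr::read_lines(baits)
  }
  if (is.null(baits)) baits <- sort(unique(runs$bait))

  scored <- stage("score", {
    if (is.null(scored)) {
      if (is.null(controls)) {
        abort("Either scored interactions or control runs must be supplied")
      }
      surrogate_score(runs, controls)
    } else {
      as_input(scored, read_saint)
    }
  })

  distilled <- stage("distill",
                     distill_interactome(scored, crapome, thresholds))
  kept <- distilled$interactions
  write_interactions(dplyr::select(distilled$decisions, -"crapome_freq",
                                   -"crapome_avg"),
                     file.path(out_dir, "decisions.tsv"))
  write_interactions(kept, file.path(out_dir, "interactions.tsv"))

  qc <- stage("qc", replicate_report(runs))
  readr::write_tsv(qc, file.path(out_dir, "qc.tsv"), progress = FALSE)

  bioid <- kept[kept$method == "BioID", ]
  apms <- kept[kept$method == "AP-MS", ]
  net <- stage("network", build_network(bioid, apms))
  if (!is.null(references)) net <- annotate_known(net, references)
  readr::write_tsv(net, file.path(out_dir, "edges.tsv"), progress = FALSE)

  overlap <- method_overlap_counts(bioid, apms)
  degree <- prey_degree(net)
  readr::write_tsv(degree, file.path(out_dir, "prey_degree.tsv"),
                   progress = FALSE)
  bb <- bait_bait_edges(net, baits)
  readr::write_tsv(bb, file.path(out_dir, "bait_bait.tsv"), progress = FALSE)
  bidir <- bidirectional_pairs(bb)
  nfi <- nfi_partition(bb, baits)
  readr::write_tsv(nfi, file.path(out_dir, "nfi_partition.tsv"),
                   progress = FALSE)

  summary <- list(
    n_runs = nrow(dplyr::distinct(runs, .data$bait, .data$method,
                                  .data$bio_rep, .data$tech_rep)),
    n_scored = nrow(scored),
    n_kept = nrow(kept),
    n_bioid = nrow(bioid),
    n_apms = nrow(apms),
    overlap = as.list(overlap),
    n_bait_bait = nrow(bb),
    n_bidirectional = nrow(bidir),
    nfi_classes = as.list(table(nfi$class)),
    median_replicate_r = if (nrow(qc) > 0) stats::median(qc$r) else NA,
    thresholds = unclass(thresholds)
  )

  if (!is.null(references)) {
    kf <- known_fractions(net)
    readr::write_tsv(kf, file.path(out_dir, "known_fractions.tsv"),
                     progress = FALSE)
    summary$known_fractions <- as.list(stats::setNames(kf$fraction_known,
                                                       kf$method))
  }
  if (!is.null(localization)) {
    loc <- localization_fraction(net, localization)
    readr::write_tsv(loc, file.path(out_dir, "localization.tsv"),
                     progress = FALSE)
    summary$fraction_nuclear <- loc$fraction_nuclear
  }
  if (!is.null(complexes)) {
    cov <- complex_coverage(net, complexes)
    readr::write_tsv(cov, file.path(out_dir, "complex_coverage.tsv"),
                     progress = FALSE)
  }
  if (!is.null(cluster_k)) {
    mat <- build_bait_prey_matrix(bioid)
    if (nrow(mat) >= 2 && ncol(mat) >= max(2, cluster_k)) {
      cl <- stage("cluster", {
        cm <- prey_correlation_matrix(mat)
        hc <- stats::hclust(stats::dist(cm), method = "average")
        extract_clusters(hc, k = cluster_k)
      })
      readr::write_tsv(tidy(cl), file.path(out_dir, "clusters.tsv"),
                       progress = FALSE)
      drivers <- driving_baits(cl, bioid)
      readr::write_tsv(drivers, file.path(out_dir, "driving_baits.tsv"),
                       progress = FALSE)
      summary$cluster_sizes <- as.list(table(cl$cluster))
    }
  }
  if (!is.null(gene_sets) && nrow(bioid) > 0) {
    background <- unique(bioid$prey)
    enr <- stage("enrich", {
      purrr::map_dfr(sort(unique(bioid$bait)), function(b) {
        res <- suppressWarnings(
          enrich(bioid$prey[bioid$bait == b], background, gene_sets))
        dplyr::mutate(res, bait = b, .before = 1)
      })
    })
    readr::write_tsv(enr, file.path(out_dir, "enrichment.tsv"),
                     progress = FALSE)
    summary$n_enriched_fdr05 <- sum(enr$fdr <= 0.05)
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
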