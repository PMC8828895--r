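# Readers and writers for every external table the pipeline touches.
# All files are tab-separated UTF-8 with a single header line, matching the
# SAINTexpress / CRAPome export ecosystem. Gene identifiers are opaque,
# case-sensitive strings; no symbol mapping is attempted.

read_tsv_quiet <- function(path, col_types) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "tfdistill_format_error")
  }
  readr::read_tsv(path, col_types = col_types, progress = FALSE)
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(paste0(
      "File '", path, "' is missing required column(s): ",
      paste(missing, collapse = ", ")
    ), class = "tfdistill_format_error")
  }
  invisible(df)
}

#' Read bait purification runs
#'
#' Reads a long-format table of spectral counts, one row per
#' (bait, method, replicate, prey) observation. Counts for a prey repeated
#' within the same run are summed. A run is identified by the combination of
#' bait, method, biological replicate and technical replicate.
#'
#' @param path Path to a tab-separated file with columns `bait`, `method`
#'   (`"BioID"` or `"AP-MS"`), `bio_rep`, `tech_rep`, `prey`,
#'   `spectral_count` (non-negative integers; peptide-spectrum matches).
#' @return A tibble with one row per (bait, method, bio_rep, tech_rep, prey)
#'   and a `spectral_count` column.
#' @export
#' @examples
#' tf <- system.file("extdata", "demo_runs.tsv", package = "tfdistill")
#' read_runs(tf)
read_runs <- function(path) {
  df <- read_tsv_quiet(path, readr::cols(
    bait = readr::col_character(),
    method = readr::col_character(),
    bio_rep = readr::col_integer(),
    tech_rep = readr::col_integer(),
    prey = readr::col_character(),
    spectral_count = readr::col_double()
  ))
  require_columns(df, c("bait", "method", "bio_rep", "tech_rep", "prey",
                        "spectral_count"), path)
  if (nrow(df) == 0) {
    return(df)
  }
  check_method(df$method)
  check_nonneg(df$spectral_count, "spectral_count", path)
  if (any(df$bio_rep < 1) || any(df$tech_rep < 1)) {
    abort("Replicate indices must be >= 1", class = "tfdistill_validation_error")
  }
  df %>%
    dplyr::group_by(.data$bait, .data$method, .data$bio_rep, .data$tech_rep,
                    .data$prey) %>%
    dplyr::summarise(spectral_count = sum(.data$spectral_count),
                     .groups = "drop")
}

#' Read GFP control runs
#'
#' Control purifications (GFP or nuclear-localized GFP-NLS baits) used as the
#' negative-control panel for scoring and contaminant profiling.
#'
#' @param path Tab-separated file with columns `control_id`, `control_type`
#'   (`"GFP"` or `"GFP-NLS"`), `method`, `prey`, `spectral_count`.
#' @return A tibble, counts within a control run summed per prey.
#' @export
read_control_runs <- function(path) {
  df <- read_tsv_quiet(path, readr::cols(
    control_id = readr::col_character(),
    control_type = readr::col_character(),
    method = readr::col_character(),
    prey = readr::col_character(),
    spectral_count = readr::col_double()
  ))
  require_columns(df, c("control_id", "control_type", "method", "prey",
                        "spectral_count"), path)
  if (nrow(df) == 0) return(df)
  check_method(df$method)
  bad_type <- setdiff(unique(df$control_type), c("GFP", "GFP-NLS"))
  if (length(bad_type) > 0) {
    abort(paste0("Unknown control_type: ", paste(bad_type, collapse = ", ")),
          class = "tfdistill_validation_error")
  }
  check_nonneg(df$spectral_count, "spectral_count", path)
  df %>%
    dplyr::group_by(.data$control_id, .data$control_type, .data$method,
                    .data$prey) %>%
    dplyr::summarise(spectral_count = sum(.data$spectral_count),
                     .groups = "drop")
}

#' Read SAINTexpress-style scored interactions
#'
#' Parses the "list" output dialect of SAINTexpress: one row per (bait, prey)
#' with the average spectral count across the bait's runs and the SAINT
#' confidence score in \[0, 1\].
#'
#' @param path Tab-separated file with columns `Bait`, `Prey`, `AvgSpec`,
#'   `SaintScore`, and optionally `Method`.
#' @param method Method label to assign when the file carries no `Method`
#'   column (default `"BioID"`).
#' @return A tibble with columns `bait`, `prey`, `method`, `avg_spec`,
#'   `saint_score`.
#' @export
read_saint <- function(path, method = "BioID") {
  df <- read_tsv_quiet(path, readr::cols(.default = readr::col_guess()))
  require_columns(df, c("Bait", "Prey", "AvgSpec", "SaintScore"), path)
  out <- tibble(
    bait = as.character(df$Bait),
    prey = as.character(df$Prey),
    method = if ("Method" %in% names(df)) as.character(df$Method) else method,
    avg_spec = as.numeric(df$AvgSpec),
    saint_score = as.numeric(df$SaintScore)
  )
  if (nrow(out) == 0) return(out)
  check_method(out$method)
  check_nonneg(out$avg_spec, "AvgSpec", path)
  bad <- which(is.na(out$saint_score) | out$saint_score < 0 | out$saint_score > 1)
  if (length(bad) > 0) {
    abort(paste0("SaintScore outside [0, 1] at row(s) ",
                 paste(utils::head(bad, 5), collapse = ", ")),
          class = "tfdistill_validation_error")
  }
  dup <- out %>%
    dplyr::count(.data$bait, .data$prey, .data$method) %>%
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("Duplicate (bait, prey) pair(s): ",
                 paste(paste0(dup$bait, "-", dup$prey)[seq_len(min(5, nrow(dup)))],
                       collapse = ", ")),
          class = "tfdistill_validation_error")
  }
  out
}

#' Write scored interactions in the SAINTexpress list dialect
#'
#' @param interactions Tibble with columns `bait`, `prey`, `method`,
#'   `avg_spec`, `saint_score`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_saint <- function(interactions, path) {
  out <- tibble(
    Bait = interactions$bait,
    Prey = interactions$prey,
    Method = interactions$method,
    AvgSpec = interactions$avg_spec,
    SaintScore = interactions$saint_score
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a CRAPome-style contaminant profile
#'
#' Each prey's detection count out of a number of negative-control
#' experiments (716 in CRAPome v2.0) and its average spectral count in the
#' controls where it was seen. Preys absent from the table are treated
#' downstream as never-detected (frequency 0): absence from a contaminant
#' repository is evidence of non-contamination.
#'
#' @param path Tab-separated file with columns `prey`, `n_detected`,
#'   `n_experiments`, `avg_spectral_count`.
#' @return A tibble with those columns plus a derived `frequency` column.
#' @export
read_crapome <- function(path) {
  df <- read_tsv_quiet(path, readr::cols(
    prey = readr::col_character(),
    n_detected = readr::col_double(),
    n_experiments = readr::col_double(),
    avg_spectral_count = readr::col_double()
  ))
  require_columns(df, c("prey", "n_detected", "n_experiments",
                        "avg_spectral_count"), path)
  if (nrow(df) == 0) {
    return(dplyr::mutate(df, frequency = numeric(0)))
  }
  check_nonneg(df$n_detected, "n_detected", path)
  check_nonneg(df$avg_spectral_count, "avg_spectral_count", path)
  bad <- which(df$n_detected > df$n_experiments)
  if (length(bad) > 0) {
    abort(paste0("n_detected exceeds n_experiments at row(s) ",
                 paste(utils::head(bad, 5), collapse = ", ")),
          class = "tfdistill_validation_error")
  }
  dplyr::mutate(df, frequency = .data$n_detected / .data$n_experiments)
}

#' Read gene sets from a GMT file
#'
#' Standard tab-separated gene-set format: term id, description, then one
#' gene per remaining field. Returned long (one row per term-gene pair) so
#' the sets compose with dplyr verbs.
#'
#' @param path Path to a GMT file.
#' @return Tibble with columns `term_id`, `term_name`, `gene`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "tfdistill_format_error")
  }
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(term_id = character(), term_name = character(),
                  gene = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, integer(1)) < 3)
  if (length(short) > 0) {
    abort(paste0("Malformed GMT line (fewer than 3 fields) at line(s) ",
                 paste(utils::head(short, 5), collapse = ", ")),
          class = "tfdistill_format_error")
  }
  purrr::map_dfr(fields, function(f) {
    tibble(term_id = f[1], term_name = f[2], gene = unique(f[-(1:2)]))
  })
}

#' Write gene sets to a GMT file
#'
#' @param gene_sets Tibble with columns `term_id`, `term_name`, `gene`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- gene_sets %>%
    dplyr::group_by(.data$term_id, .data$term_name) %>%
    dplyr::summarise(line = paste(c(.data$term_id[1], .data$term_name[1],
                                    .data$gene), collapse = "\t"),
                     .groups = "drop") %>%
    dplyr::pull(.data$line)
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read an undirected PPI edge list
#'
#' Two-column reference edge list (e.g. a PINA2 / STRING / IntAct / BioGRID
#' export). Pairs are normalized so that (A, B) and (B, A) collapse to a
#' single undirected pair with `gene_a <= gene_b`; self-pairs are kept as-is.
#'
#' @param path Tab-separated file whose first two columns are gene symbols.
#' @return Tibble with columns `gene_a`, `gene_b`, one row per unique
#'   undirected pair.
#' @export
read_edge_list <- function(path) {
  df <- read_tsv_quiet(path, readr::cols(.default = readr::col_character()))
  if (ncol(df) < 2) {
    abort(paste0("Edge list '", path, "' needs at least two columns"),
          class = "tfdistill_format_error")
  }
  normalize_pairs(tibble(gene_a = df[[1]], gene_b = df[[2]]))
}

#' Normalize gene pairs to undirected form
#'
#' Orders each pair lexicographically and drops duplicates, so the result is
#' idempotent and insensitive to the original orientation.
#'
#' @param pairs Tibble with columns `gene_a`, `gene_b`.
#' @return Tibble of unique pairs with `gene_a <= gene_b`.
#' @export
normalize_pairs <- function(pairs) {
  if (nrow(pairs) == 0) {
    return(tibble(gene_a = character(), gene_b = character()))
  }
  tibble(
    gene_a = pmin(pairs$gene_a, pairs$gene_b),
    gene_b = pmax(pairs$gene_a, pairs$gene_b)
  ) %>%
    dplyr::distinct()
}

#' Read a prey localization table
#'
#' @param path Tab-separated file with columns `prey`, `compartment`;
#'   multi-localized preys occupy several rows.
#' @return Tibble with those columns.
#' @export
read_localization <- function(path) {
  df <- read_tsv_quiet(path, readr::cols(
    prey = readr::col_character(),
    compartment = readr::col_character()
  ))
  require_columns(df, c("prey", "compartment"), path)
  dplyr::distinct(df)
}

#' Read protein-complex definitions
#'
#' CORUM-style complex membership, long format.
#'
#' @param path Tab-separated file with columns `complex_name`, `subunit`.
#' @return Tibble with those columns.
#' @export
read_complexes <- function(path) {
  df <- read_tsv_quiet(path, readr::cols(
    complex_name = readr::col_character(),
    subunit = readr::col_character()
  ))
  require_columns(df, c("complex_name", "subunit"), path)
  dplyr::distinct(df)
}

#' Write / read a distilled interaction table
#'
#' The distilled table carries the surviving high-confidence edges with their
#' provenance: bait, prey, method, average spectral count, SAINT score, the
#' filter decision and (optionally) a known-interaction flag.
#'
#' @param interactions Tibble with columns `bait`, `prey`, `method`,
#'   `avg_spec`, `saint_score`, and optionally `decision` and `known`.
#' @param path File path.
#' @return `write_interactions()` returns `path` invisibly;
#'   `read_interactions()` returns the tibble.
#' @export
write_interactions <- function(interactions, path) {
  readr::write_tsv(interactions, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_interactions
#' @export
read_interactions <- function(path) {
  df <- read_tsv_quiet(path, readr::cols(
    bait = readr::col_character(),
    prey = readr::col_character(),
    method = readr::col_character(),
    avg_spec = readr::col_double(),
    saint_score = readr::col_double(),
    .default = readr::col_guess()
  ))
  require_columns(df, c("bait", "prey", "method", "avg_spec", "saint_score"),
                  path)
  df
}
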