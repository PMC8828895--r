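# Synthetic spectral-count experiments with the statistical structure the
# cascade assumes: planted true bait-prey interactions, frequency-structured
# contaminants shared with negative-control runs, replicate noise, and a
# CRAPome-style contaminant profile derived from the controls. Counts are
# negative-binomial to emulate the overdispersion of spectral counts.

#' Simulation configuration
#'
#' Defaults describe the study conditions the analysis was designed for:
#' two biological x two technical replicates per bait, 16 negative-control
#' runs (the nuclear-localized control panel size for proximity labeling),
#' a contaminant profile scaled to 716 control experiments so the 50% and
#' 25-50% frequency bands are exercised on their native scale, and
#' negative-binomial counts with mean 15 for true partners.
#'
#' @param n_baits Number of bait TFs.
#' @param n_preys Size of the true-prey pool (non-contaminant).
#' @param n_contaminants Number of background contaminant proteins.
#' @param true_edge_prob Probability that a given bait-prey pair is a
#'   planted true interaction.
#' @param mean_true_count Negative-binomial mean spectral count of a true
#'   partner in one run.
#' @param dispersion Negative-binomial size parameter (smaller = more
#'   overdispersed); shared by true and contaminant counts.
#' @param contam_freq_range Range of per-contaminant detection
#'   probabilities, drawn uniformly.
#' @param mean_contam_count Mean spectral count of a contaminant in a run
#'   where it is detected.
#' @param n_bio_reps,n_tech_reps Replicate structure per bait.
#' @param n_controls Number of GFP/GFP-NLS control runs.
#' @param n_experiments Experiment count the contaminant profile is scaled
#'   to (CRAPome-style denominator).
#' @param method Purification method label for all generated runs.
#' @param planted_modules Optional list of module specs, each a list with
#'   `n_preys` (module size) and `baits` (bait indices sharing the module).
#'   Module preys interact with exactly the module's baits, giving the
#'   block-correlation structure prey-prey clustering should recover.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_baits = 6,
                       n_preys = 80,
                       n_contaminants = 60,
                       true_edge_prob = 0.15,
                       mean_true_count = 15,
                       dispersion = 4,
                       contam_freq_range = c(0.05, 0.95),
                       mean_contam_count = 8,
                       n_bio_reps = 2,
                       n_tech_reps = 2,
                       n_controls = 16,
                       n_experiments = 716,
                       method = "BioID",
                       planted_modules = NULL) {
  stopifnot_positive <- function(x, name) {
    if (length(x) != 1 || is.na(x) || x < 1) {
      abort(paste0(name, " must be a single value >= 1"),
            class = "tfdistill_validation_error")
    }
  }
  stopifnot_positive(n_baits, "n_baits")
  stopifnot_positive(n_preys, "n_preys")
  stopifnot_positive(n_contaminants, "n_contaminants")
  stopifnot_positive(n_bio_reps, "n_bio_reps")
  stopifnot_positive(n_tech_reps, "n_tech_reps")
  stopifnot_positive(n_controls, "n_controls")
  stopifnot_positive(n_experiments, "n_experiments")
  if (true_edge_prob < 0 || true_edge_prob > 1) {
    abort("true_edge_prob must lie in [0, 1]",
          class = "tfdistill_validation_error")
  }
  if (dispersion <= 0) {
    abort("dispersion must be positive", class = "tfdistill_validation_error")
  }
  if (length(contam_freq_range) != 2 || any(contam_freq_range < 0) ||
      any(contam_freq_range > 1) ||
      contam_freq_range[1] > contam_freq_range[2]) {
    abort("contam_freq_range must be an increasing pair within [0, 1]",
          class = "tfdistill_validation_error")
  }
  check_method(method)
  if (!is.null(planted_modules)) {
    for (m in planted_modules) {
      if (is.null(m$n_preys) || is.null(m$baits) ||
          any(m$baits < 1) || any(m$baits > n_baits)) {
        abort("Each planted module needs n_preys and valid bait indices",
              class = "tfdistill_validation_error")
      }
    }
  }
  structure(
    list(n_baits = n_baits, n_preys = n_preys,
         n_contaminants = n_contaminants, true_edge_prob = true_edge_prob,
         mean_true_count = mean_true_count, dispersion = dispersion,
         contam_freq_range = contam_freq_range,
         mean_contam_count = mean_contam_count,
         n_bio_reps = n_bio_reps, n_tech_reps = n_tech_reps,
         n_controls = n_controls, n_experiments = n_experiments,
         method = method, planted_modules = planted_modules),
    class = "sim_config"
  )
}

# detected-contaminant count: at least 1 PSM given detection
rcontam_count <- function(n, config) {
  1 + stats::rnbinom(n, mu = max(config$mean_contam_count - 1, 0.1),
                     size = config$dispersion)
}

#' Generate a synthetic spectral-count experiment
#'
#' Draws planted true interactions, contaminant detections in bait and
#' control runs, and summarizes the control runs into a CRAPome-style
#' profile scaled to `n_experiments`. The same seed reproduces the output
#' exactly.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; all randomness flows from it.
#' @return A list of class `tf_simulation` with elements `runs`
#'   ([read_runs()] layout), `controls` ([read_control_runs()] layout),
#'   `crapome` ([read_crapome()] layout), and `truth` (list with
#'   `planted_edges`, `contaminants` incl. nominal control frequencies,
#'   `config`, `seed`).
#' @export
#' @examples
#' sim <- simulate_experiment(sim_config(n_baits = 2, n_preys = 10,
#'                                       n_contaminants = 5), seed = 1)
#' head(sim$runs)
simulate_experiment <- function(config = sim_config(), seed = 1) {
  if (!inherits(config, "sim_config")) {
    abort("config must be built with sim_config()",
          class = "tfdistill_validation_error")
  }
  withr::with_seed(as.integer(seed), {
    baits <- sprintf("TF%02d", seq_len(config$n_baits))
    true_preys <- sprintf("PRY%03d", seq_len(config$n_preys))
    contaminants <- sprintf("CON%03d", seq_len(config$n_contaminants))

    # planted random edges on the true-prey pool
    grid <- tidyr::expand_grid(bait = baits, prey = true_preys)
    planted <- grid[stats::runif(nrow(grid)) < config$true_edge_prob, ]

    # planted module edges: module preys interact with exactly their baits
    if (!is.null(config$planted_modules)) {
      module_edges <- purrr::imap_dfr(config$planted_modules, function(m, i) {
        mp <- sprintf("MOD%d_%02d", i, seq_len(m$n_preys))
        tidyr::expand_grid(bait = baits[m$baits], prey = mp)
      })
      module_truth <- purrr::imap_dfr(config$planted_modules, function(m, i) {
        tibble(prey = sprintf("MOD%d_%02d", i, seq_len(m$n_preys)),
               module = i)
      })
      planted <- dplyr::bind_rows(planted, module_edges)
    } else {
      module_truth <- tibble(prey = character(), module = integer())
    }

    contam_freq <- stats::runif(config$n_contaminants,
                                config$contam_freq_range[1],
                                config$contam_freq_range[2])
    contam_tbl <- tibble(prey = contaminants, control_freq = contam_freq)

    rep_grid <- tidyr::expand_grid(
      bait = baits,
      bio_rep = seq_len(config$n_bio_reps),
      tech_rep = seq_len(config$n_tech_reps)
    )

    # true-partner counts per run
    true_rows <- rep_grid %>%
      dplyr::inner_join(planted, by = "bait",
                        relationship = "many-to-many") %>%
      dplyr::mutate(spectral_count = stats::rnbinom(
        dplyr::n(), mu = config$mean_true_count, size = config$dispersion))

    # contaminant detections per bait run
    contam_rows <- rep_grid %>%
      tidyr::expand_grid(contam_tbl) %>%
      dplyr::mutate(detected = stats::runif(dplyr::n()) < .data$control_freq) %>%
      dplyr::filter(.data$detected)
    contam_rows$spectral_count <- rcontam_count(nrow(contam_rows), config)

    runs <- dplyr::bind_rows(
      dplyr::select(true_rows, "bait", "bio_rep", "tech_rep", "prey",
                    "spectral_count"),
      dplyr::select(contam_rows, "bait", "bio_rep", "tech_rep", "prey",
                    "spectral_count")
    ) %>%
      dplyr::filter(.data$spectral_count > 0) %>%
      dplyr::mutate(method = config$method) %>%
      dplyr::select("bait", "method", "bio_rep", "tech_rep", "prey",
                    "spectral_count") %>%
      dplyr::arrange(.data$bait, .data$bio_rep, .data$tech_rep, .data$prey)

    # control runs: contaminants only
    ctrl_ids <- sprintf("CTRL%02d", seq_len(config$n_controls))
    ctrl_types <- rep(c("GFP", "GFP-NLS"),
                      length.out = config$n_controls)
    ctrl_rows <- tidyr::expand_grid(control_id = ctrl_ids, contam_tbl) %>%
      dplyr::mutate(detected = stats::runif(dplyr::n()) < .data$control_freq) %>%
      dplyr::filter(.data$detected)
    ctrl_rows$spectral_count <- rcontam_count(nrow(ctrl_rows), config)
    controls <- ctrl_rows %>%
      dplyr::mutate(
        control_type = ctrl_types[match(.data$control_id, ctrl_ids)],
        method = config$method
      ) %>%
      dplyr::select("control_id", "control_type", "method", "prey",
                    "spectral_count") %>%
      dplyr::arrange(.data$control_id, .data$prey)

    # CRAPome-style profile from control detections, scaled to n_experiments
    crapome <- controls %>%
      dplyr::group_by(.data$prey) %>%
      dplyr::summarise(
        n_det_ctrl = dplyr::n(),
        avg_spectral_count = mean(.data$spectral_count),
        .groups = "drop"
      ) %>%
      dplyr::mutate(
        n_detected = round(.data$n_det_ctrl / config$n_controls *
                             config$n_experiments),
        n_experiments = config$n_experiments,
        frequency = .data$n_detected / .data$n_experiments
      ) %>%
      dplyr::select("prey", "n_detected", "n_experiments",
                    "avg_spectral_count", "frequency")

    structure(
      list(
        runs = runs,
        controls = controls,
        crapome = crapome,
        truth = list(
          planted_edges = dplyr::arrange(planted, .data$bait, .data$prey),
          contaminants = contam_tbl,
          modules = module_truth,
          config = config,
          seed = as.integer(seed)
        )
      ),
      class = "tf_simulation"
    )
  })
}

#' @export
print.tf_simulation <- function(x, ...) {
  cat("<tf_simulation>\n")
  cat("  baits:", x$truth$config$n_baits,
      " planted edges:", nrow(x$truth$planted_edges),
      " contaminants:", nrow(x$truth$contaminants), "\n")
  cat("  runs:", nrow(dplyr::distinct(x$runs, .data$bait, .data$bio_rep,
                                      .data$tech_rep)),
      " control runs:", length(unique(x$controls$control_id)), "\n")
  invisible(x)
}

#' Precision and recall of a distilled table against the planted truth
#'
#' @param interactions Distilled interaction tibble (`bait`, `prey`).
#' @param truth Truth list from [simulate_experiment()] (or any list with a
#'   `planted_edges` tibble).
#' @return One-row tibble: `tp`, `fp`, `fn`, `precision` (NA when nothing
#'   was distilled), `recall`.
#' @export
evaluate_recovery <- function(interactions, truth) {
  got <- unique(paste(interactions$bait, interactions$prey, sep = "\r"))
  want <- unique(paste(truth$planted_edges$bait, truth$planted_edges$prey,
                       sep = "\r"))
  tp <- length(intersect(got, want))
  tibble(
    tp = tp,
    fp = length(got) - tp,
    fn = length(want) - tp,
    precision = if (length(got) == 0) NA_real_ else tp / length(got),
    recall = if (length(want) == 0) NA_real_ else tp / length(want)
  )
}
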