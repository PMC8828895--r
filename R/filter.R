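# The confidence cascade that distills high-confidence interactomes:
# a SAINT-score threshold followed by method-specific CRAPome contaminant
# rules. BioID and AP-MS edges face different contaminant logic because
# proximity labeling and affinity purification have different background
# structure.

#' Filtering thresholds for the confidence cascade
#'
#' Bundles the tunable constants of the cascade. The defaults are the
#' study-standard values: SAINT score cutoff 0.74, CRAPome high-frequency
#' band at 50% (358 of 716 control experiments), mid band starting at 25%
#' (179/716), and a threefold spectral-count requirement for high-frequency
#' AP-MS preys.
#'
#' Boundary conventions (configuration-exposed because the prose rules leave
#' them open): the SAINT cutoff is inclusive (score >= cutoff is kept); for
#' BioID a frequency of exactly 50% is dropped and the mid band is
#' `[freq_mid, freq_high)`; for AP-MS the fold rule fires only at frequency
#' strictly above `freq_high`, and "threefold higher" is inclusive
#' (study average >= fold x CRAPome average passes).
#'
#' @param saint_cutoff Minimum SAINT score kept (default 0.74).
#' @param freq_high High CRAPome frequency boundary (default 0.50).
#' @param freq_mid Lower edge of the mid-frequency band (default 0.25).
#' @param apms_fold Fold requirement for high-frequency AP-MS preys
#'   (default 3).
#' @return A list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(saint_cutoff = 0.74, freq_high = 0.50,
                              freq_mid = 0.25, apms_fold = 3.0) {
  if (!(saint_cutoff >= 0 && saint_cutoff <= 1)) {
    abort("saint_cutoff must lie in [0, 1]", class = "tfdistill_validation_error")
  }
  if (!(freq_mid >= 0 && freq_mid < freq_high && freq_high <= 1)) {
    abort("Need 0 <= freq_mid < freq_high <= 1",
          class = "tfdistill_validation_error")
  }
  if (apms_fold <= 0) {
    abort("apms_fold must be positive", class = "tfdistill_validation_error")
  }
  structure(
    list(saint_cutoff = saint_cutoff, freq_high = freq_high,
         freq_mid = freq_mid, apms_fold = apms_fold),
    class = "filter_thresholds"
  )
}

#' Average spectral counts per bait and prey
#'
#' For each bait and method, the arithmetic mean of a prey's spectral counts
#' over all of that bait's runs (biological and technical replicates pooled),
#' substituting zero in runs where the prey was not observed. This is the
#' "average spectral count" the contaminant rules compare against the
#' CRAPome averages.
#'
#' @param runs Run tibble as returned by [read_runs()].
#' @return Tibble with columns `bait`, `method`, `prey`, `avg_spec`,
#'   `n_runs`.
#' @export
average_spectral_counts <- function(runs) {
  if (nrow(runs) == 0) {
    abort("No runs supplied", class = "tfdistill_validation_error")
  }
  n_runs <- runs %>%
    dplyr::distinct(.data$bait, .data$method, .data$bio_rep, .data$tech_rep) %>%
    dplyr::count(.data$bait, .data$method, name = "n_runs")
  runs %>%
    dplyr::group_by(.data$bait, .data$method, .data$prey) %>%
    dplyr::summarise(total = sum(.data$spectral_count), .groups = "drop") %>%
    dplyr::left_join(n_runs, by = c("bait", "method")) %>%
    dplyr::mutate(avg_spec = .data$total / .data$n_runs) %>%
    dplyr::select("bait", "method", "prey", "avg_spec", "n_runs")
}

# Attach CRAPome frequency/average columns, with the implicit-zero fallback
# for preys absent from the profile.
join_crapome <- function(interactions, crapome) {
  lookup <- crapome %>%
    dplyr::select("prey", crapome_freq = "frequency",
                  crapome_avg = "avg_spectral_count")
  interactions %>%
    dplyr::left_join(lookup, by = "prey") %>%
    dplyr::mutate(
      crapome_freq = dplyr::coalesce(.data$crapome_freq, 0),
      crapome_avg = dplyr::coalesce(.data$crapome_avg, 0)
    )
}

# Vectorized rule dispatch; assumes SAINT stage already passed.
crapome_rule <- function(method, avg_spec, crapome_freq, crapome_avg,
                         thresholds) {
  t <- thresholds
  dplyr::case_when(
    method == "BioID" & crapome_freq >= t$freq_high ~ "bioid_freq_ge_high",
    method == "BioID" & crapome_freq >= t$freq_mid &
      crapome_avg > avg_spec ~ "bioid_midband_crapome_higher",
    method == "AP-MS" & crapome_freq > t$freq_high &
      avg_spec < t$apms_fold * crapome_avg ~ "apms_highfreq_below_fold",
    TRUE ~ "pass"
  )
}

#' Apply the SAINT score threshold
#'
#' First stage of the cascade: interactions with `saint_score >= saint_cutoff`
#' survive; the rest are recorded with rule `saint_fail`.
#'
#' @param interactions Scored-interaction tibble (`bait`, `prey`, `method`,
#'   `avg_spec`, `saint_score`).
#' @param thresholds A [filter_thresholds()] object.
#' @return The input tibble with logical `kept` and character `rule` columns
#'   (`"pass"` here means "passed this stage").
#' @export
apply_saint_threshold <- function(interactions, thresholds = filter_thresholds()) {
  interactions %>%
    dplyr::mutate(
      kept = .data$saint_score >= thresholds$saint_cutoff,
      rule = dplyr::if_else(.data$kept, "pass", "saint_fail")
    )
}

#' Distill the high-confidence interactome
#'
#' Runs the full confidence cascade over scored interactions: the SAINT
#' threshold, then the method-specific CRAPome contaminant rules.
#'
#' For BioID, preys at CRAPome frequency >= `freq_high` are removed
#' outright, and preys in the mid band (`freq_mid` to `freq_high`) are
#' removed when their CRAPome average spectral count exceeds the study
#' average. For AP-MS, preys above `freq_high` must carry at least
#' `apms_fold` times the CRAPome average spectral count. Preys missing from
#' the CRAPome profile are treated as frequency 0.
#'
#' Every input interaction receives exactly one decision rule, one of
#' `pass`, `saint_fail`, `bioid_freq_ge_high`, `bioid_midband_crapome_higher`,
#' `apms_highfreq_below_fold`.
#'
#' @param interactions Scored-interaction tibble (`bait`, `prey`, `method`,
#'   `avg_spec`, `saint_score`).
#' @param crapome Contaminant profile from [read_crapome()] (may be empty).
#' @param thresholds A [filter_thresholds()] object.
#' @return An object of class `tf_distilled`: a list with `interactions`
#'   (the surviving edges), `decisions` (every input edge with `kept` and
#'   `rule`), and `thresholds`. Use [tidy()] / [glance()] to extract tibbles.
#' @export
#' @examples
#' scored <- tibble::tibble(
#'   bait = "TP53", prey = c("KDM2B", "HSPA8", "EP300"),
#'   method = "BioID", avg_spec = c(12.5, 3, 8),
#'   saint_score = c(0.99, 0.95, 0.5)
#' )
#' crapome <- tibble::tibble(
#'   prey = "HSPA8", n_detected = 600, n_experiments = 716,
#'   avg_spectral_count = 45.2, frequency = 600 / 716
#' )
#' distill_interactome(scored, crapome)
distill_interactome <- function(interactions, crapome = NULL,
                                thresholds = filter_thresholds()) {
  check_method(interactions$method)
  if (is.null(crapome) || nrow(crapome) == 0) {
    crapome <- tibble(prey = character(), n_detected = numeric(),
                      n_experiments = numeric(),
                      avg_spectral_count = numeric(), frequency = numeric())
  }
  staged <- join_crapome(interactions, crapome)
  decisions <- staged %>%
    dplyr::mutate(
      rule = dplyr::if_else(
        .data$saint_score < thresholds$saint_cutoff,
        "saint_fail",
        crapome_rule(.data$method, .data$avg_spec, .data$crapome_freq,
                     .data$crapome_avg, thresholds)
      ),
      kept = .data$rule == "pass"
    )
  kept <- decisions %>%
    dplyr::filter(.data$kept) %>%
    dplyr::select(-"kept", -"rule", -"crapome_freq", -"crapome_avg")
  structure(
    list(interactions = kept, decisions = decisions, thresholds = thresholds),
    class = "tf_distilled"
  )
}

#' @export
print.tf_distilled <- function(x, ...) {
  cat("<tf_distilled> high-confidence interactome\n")
  cat("  kept:", nrow(x$interactions), "of", nrow(x$decisions),
      "scored interactions\n")
  tab <- table(x$decisions$rule)
  for (r in names(tab)) cat("   ", r, ":", tab[[r]], "\n")
  invisible(x)
}

#' Surrogate interaction scorer
#'
#' A simple monotone confidence score used when SAINTexpress output is not
#' available, so the cascade can run end-to-end from raw runs. For each prey
#' of a bait it compares the bait-average spectral count `b` (zeros
#' substituted over all the bait's runs) to the maximum control count `c`
#' observed for that prey across the negative-control runs:
#'
#'   score = b^2 / (b^2 + (c + 1)^2)
#'
#' The score is 0 when the prey is absent from the bait runs, rises
#' monotonically with `b`, approaches 1 when `b` far exceeds the control
#' maximum, and is below 0.5 whenever `b <= c`. It is a heuristic ranking
#' statistic, not a posterior probability.
#'
#' @param runs Bait runs ([read_runs()] layout).
#' @param controls Control runs ([read_control_runs()] layout); must be
#'   non-empty.
#' @return Scored-interaction tibble (`bait`, `prey`, `method`, `avg_spec`,
#'   `saint_score`) suitable for [distill_interactome()].
#' @export
surrogate_score <- function(runs, controls) {
  if (nrow(runs) == 0) {
    abort("No bait runs supplied", class = "tfdistill_validation_error")
  }
  if (is.null(controls) || nrow(controls) == 0) {
    abort(paste0("No control runs supplied; surrogate scoring needs negative ",
                 "controls. Use read_saint() if you have SAINTexpress output."),
          class = "tfdistill_validation_error")
  }
  ctrl_max <- controls %>%
    dplyr::group_by(.data$prey) %>%
    dplyr::summarise(ctrl_max = max(.data$spectral_count), .groups = "drop")
  average_spectral_counts(runs) %>%
    dplyr::left_join(ctrl_max, by = "prey") %>%
    dplyr::mutate(
      ctrl_max = dplyr::coalesce(.data$ctrl_max, 0),
      saint_score = .data$avg_spec^2 /
        (.data$avg_spec^2 + (.data$ctrl_max + 1)^2)
    ) %>%
    dplyr::select("bait", "method", "prey", "avg_spec", "saint_score")
}
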