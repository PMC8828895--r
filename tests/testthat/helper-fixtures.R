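# Shared in-code fixtures: tiny tables exercising each stage, written to
# temp files where a reader is under test.

toy_runs <- function() {
  tibble::tibble(
    bait = c("TP53", "TP53", "TP53", "TP53", "MYC", "MYC"),
    method = "BioID",
    bio_rep = c(1L, 1L, 2L, 2L, 1L, 2L),
    tech_rep = 1L,
    prey = c("P1", "P2", "P1", "P3", "P1", "P1"),
    spectral_count = c(4, 6, 2, 5, 10, 14)
  )
}

toy_scored <- function() {
  tibble::tibble(
    bait = c("A", "A", "A"),
    prey = c("X", "Y", "Z"),
    method = "BioID",
    avg_spec = c(10, 8, 12),
    saint_score = c(0.9, 0.5, 0.9)
  )
}

# CRAPome profile where Z sits above the 50% band
toy_crapome <- function() {
  tibble::tibble(
    prey = "Z",
    n_detected = 430,
    n_experiments = 716,
    avg_spectral_count = 20,
    frequency = 430 / 716
  )
}

write_tsv_fixture <- function(df, name = "fixture.tsv") {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  readr::write_tsv(df, path, progress = FALSE)
  path
}

# Independent re-statement of the filtering rules, straight from the prose:
# SAINT cutoff first; BioID allows only CRAPome frequency below 50%, and in
# the 25-50% band drops preys whose CRAPome average exceeds the study
# average; AP-MS requires a threefold study-vs-CRAPome average for preys
# above 50% frequency. Evaluated one case at a time, no vectorization.
oracle_rule <- function(method, score, freq, crapome_avg, study_avg,
                        th = tfdistill::filter_thresholds()) {
  if (score < th$saint_cutoff) return("saint_fail")
  if (method == "BioID") {
    if (freq >= th$freq_high) return("bioid_freq_ge_high")
    if (freq >= th$freq_mid && crapome_avg > study_avg) {
      return("bioid_midband_crapome_higher")
    }
    return("pass")
  }
  if (freq > th$freq_high && study_avg < th$apms_fold * crapome_avg) {
    return("apms_highfreq_below_fold")
  }
  "pass"
}

# Exhaustive hypergeometric oracle: enumerate every n-subset of an N-gene
# universe whose first K genes are annotated; fraction with overlap >= k.
hypergeom_enum <- function(k, n, K, N) {
  subsets <- utils::combn(N, n)
  hits <- colSums(subsets <= K)
  mean(hits >= k)
}
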