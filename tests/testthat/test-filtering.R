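test_that("average spectral counts pool replicates with zero substitution", {
  runs <- toy_runs()
  avg <- average_spectral_counts(runs)
  # TP53 has 2 runs: P1 = (4 + 2)/2, P2 = (6 + 0)/2, P3 = (0 + 5)/2
  tp53 <- avg[avg$bait == "TP53", ]
  expect_equal(tp53$avg_spec[tp53$prey == "P1"], 3)
  expect_equal(tp53$avg_spec[tp53$prey == "P2"], 3)
  expect_equal(tp53$avg_spec[tp53$prey == "P3"], 2.5)
  # single-prey bait: mean over its 2 runs
  expect_equal(avg$avg_spec[avg$bait == "MYC"], 12)
  expect_error(average_spectral_counts(toy_runs()[0, ]),
               class = "tfdistill_validation_error")
})

test_that("SAINT threshold keeps the boundary score and drops below", {
  scored <- tibble::tibble(
    bait = "A", prey = c("P1", "P2", "P3"), method = "BioID",
    avg_spec = 5, saint_score = c(0.74, 0.7399, 0.9)
  )
  staged <- apply_saint_threshold(scored)
  expect_equal(staged$kept, c(TRUE, FALSE, TRUE))
  expect_equal(staged$rule[2], "saint_fail")
  expect_equal(nrow(apply_saint_threshold(scored[0, ])), 0)
})

test_that("BioID CRAPome rules follow the frequency bands", {
  crapome <- tibble::tibble(
    prey = c("H", "M1", "M2", "L"),
    n_detected = c(400, 200, 200, 100), n_experiments = 716,
    avg_spectral_count = c(1, 10, 2, 50),
    frequency = c(400, 200, 200, 100) / 716
  )
  scored <- tibble::tibble(
    bait = "A", prey = c("H", "M1", "M2", "L"), method = "BioID",
    avg_spec = c(100, 5, 5, 1), saint_score = 0.9
  )
  d <- distill_interactome(scored, crapome)
  rules <- setNames(d$decisions$rule, d$decisions$prey)
  expect_equal(rules[["H"]], "bioid_freq_ge_high")     # 0.559 >= 0.5
  expect_equal(rules[["M1"]], "bioid_midband_crapome_higher")
  expect_equal(rules[["M2"]], "pass")                  # mid band, study higher
  expect_equal(rules[["L"]], "pass")                   # below band
})

test_that("AP-MS fold rule fires only above 50% frequency", {
  crapome <- tibble::tibble(
    prey = c("F1", "F2", "F3"),
    n_detected = c(400, 400, 300), n_experiments = 716,
    avg_spectral_count = c(5, 5, 100),
    frequency = c(400, 400, 300) / 716
  )
  scored <- tibble::tibble(
    bait = "A", prey = c("F1", "F2", "F3"), method = "AP-MS",
    avg_spec = c(30, 10, 1), saint_score = 0.9
  )
  d <- distill_interactome(scored, crapome)
  rules <- setNames(d$decisions$rule, d$decisions$prey)
  expect_equal(rules[["F1"]], "pass")                   # 6-fold
  expect_equal(rules[["F2"]], "apms_highfreq_below_fold")
  expect_equal(rules[["F3"]], "pass")                   # freq not above 50%
})

test_that("the cascade enumerates the worked three-interaction example", {
  crapome <- tibble::tibble(prey = "Z", n_detected = 430, n_experiments = 716,
                            avg_spectral_count = 20, frequency = 430 / 716)
  d <- distill_interactome(toy_scored(), crapome)
  expect_equal(nrow(d$interactions), 1)
  expect_equal(d$interactions$prey, "X")
  expect_equal(d$decisions$rule,
               c("pass", "saint_fail", "bioid_freq_ge_high"))
})

test_that("decisions are exhaustive, mutually exclusive, and monotone", {
  set.seed(42)
  n <- 300
  scored <- tibble::tibble(
    bait = "B",
    prey = sprintf("P%03d", seq_len(n)),
    method = sample(c("BioID", "AP-MS"), n, replace = TRUE),
    avg_spec = round(runif(n, 0, 40), 1),
    saint_score = round(runif(n), 3)
  )
  crapome <- tibble::tibble(
    prey = sprintf("P%03d", seq_len(n / 2)),
    n_detected = sample(0:716, n / 2, replace = TRUE),
    n_experiments = 716,
    avg_spectral_count = round(runif(n / 2, 0, 40), 1)
  )
  crapome$frequency <- crapome$n_detected / crapome$n_experiments

  d <- distill_interactome(scored, crapome)
  expect_equal(nrow(d$decisions), n)
  expect_equal(sort(d$decisions$prey), sort(scored$prey))
  expect_equal(d$decisions$kept, d$decisions$rule == "pass")
  # distilled subset of SAINT-passing subset of input
  saint_pass <- scored$prey[scored$saint_score >= 0.74]
  expect_true(all(d$interactions$prey %in% saint_pass))
  # raising the cutoff never adds an interaction
  for (cut in c(0.5, 0.74, 0.9, 1)) {
    d2 <- distill_interactome(scored, crapome,
                              filter_thresholds(saint_cutoff = cut))
    expect_true(all(d2$interactions$prey %in%
                      distill_interactome(scored, crapome,
                                          filter_thresholds(saint_cutoff = 0))$
                      interactions$prey))
    if (cut > 0.74) {
      expect_true(all(d2$interactions$prey %in% d$interactions$prey))
    }
  }
  # determinism
  expect_identical(distill_interactome(scored, crapome)$decisions,
                   d$decisions)
})

test_that("surrogate score honors its monotonicity contract", {
  runs <- tibble::tibble(
    bait = "B", method = "BioID", bio_rep = c(1L, 2L), tech_rep = 1L,
    prey = "P", spectral_count = c(20, 20)
  )
  controls <- tibble::tibble(
    control_id = "C1", control_type = "GFP", method = "BioID",
    prey = "Q", spectral_count = 5
  )
  s <- surrogate_score(runs, controls)
  expect_gte(s$saint_score[s$prey == "P"], 0.9)   # absent from controls

  # prey seen at control levels scores at most 0.5
  runs2 <- dplyr::mutate(runs, prey = "Q", spectral_count = 5)
  s2 <- surrogate_score(runs2, controls)
  expect_lte(s2$saint_score[s2$prey == "Q"], 0.5)

  # score increases with bait abundance
  abund <- vapply(c(1, 5, 20, 100), function(a) {
    r <- dplyr::mutate(runs, spectral_count = a)
    surrogate_score(r, controls)$saint_score
  }, numeric(1))
  expect_true(all(diff(abund) > 0))

  expect_error(surrogate_score(runs, controls[0, ]), regexp = "read_saint")
})
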