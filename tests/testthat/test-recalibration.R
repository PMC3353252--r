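toy_model <- function() {
  risk_model("toy", list(term_spec("fpg", "fpg", "linear"),
                         term_spec("bmi", "bmi", "linear")),
             beta = c(1, 0.5))
}

test_that("the recalibration formula obeys its closed forms and limits", {
  m <- toy_model()
  ctx <- recal_context(m = c(fpg = 5, bmi = 23), s_m = 0.9)
  # x = m: exponent is exp(0) = 1, so p = 1 - S(m)
  s0 <- make_subjects(1, fpg = 5, bmi = 23)
  expect_equal(recalibrate(m, ctx, s0)$probability, 0.1)
  # (x - m)' beta = log 2: p = 1 - 0.9^2
  s1 <- make_subjects(1, fpg = 5 + log(2), bmi = 23)
  expect_equal(recalibrate(m, ctx, s1)$probability, 1 - 0.81)
  # limits
  lo <- make_subjects(1, fpg = 0.01, bmi = 0.5)
  hi <- make_subjects(1, fpg = 40, bmi = 23)
  expect_lt(recalibrate(m, ctx, lo)$probability, 1e-6)
  expect_gt(recalibrate(m, ctx, hi)$probability, 1 - 1e-12)
  # output always in [0, 1) and strictly increasing in the score
  grid <- make_subjects(9, fpg = seq(2, 10, by = 1), bmi = 23)
  p <- recalibrate(m, ctx, grid)$probability
  expect_true(all(p >= 0 & p < 1))
  expect_true(all(diff(p) > 0))
})

test_that("S(m) estimators anchor the local incidence", {
  cohort <- small_cohort(n = 2000, seed = 61)
  aric <- load_published_models()$ARIC
  ctx <- estimate_context(cohort, aric)
  expect_equal(ctx$s_m, 1 - mean(cohort$outcome_t2dm))
  # a stated 7.8% incidence gives S(m) = 0.922 under the plug-in rule
  fake <- cohort
  set.seed(62)
  fake$outcome_t2dm <- as.integer(seq_len(nrow(fake)) <= 0.078 * nrow(fake))
  expect_equal(estimate_context(fake, aric)$s_m, 0.922)
  # intercept-matched: mean recalibrated p equals the observed incidence
  ctx2 <- estimate_context(cohort, aric, method = "intercept_matched")
  p2 <- recalibrate(aric, ctx2, cohort)$probability
  expect_lt(abs(mean(p2) - mean(cohort$outcome_t2dm)), 1e-6)
  # agreement with an independent bisection root-find on the same
  # monotone criterion
  X <- encode_subjects(cohort, aric)
  d <- drop(X %*% aric$beta) - sum(colMeans(X) * aric$beta)
  f <- function(s) mean(1 - s^exp(d)) - mean(cohort$outcome_t2dm)
  lo <- 1e-9; hi <- 1 - 1e-9
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  expect_equal(ctx2$s_m, (lo + hi) / 2, tolerance = 1e-7)
})

test_that("a zero-event stratum gives S(m) = 1 and zero risks", {
  cohort <- small_cohort(n = 200, seed = 63)
  cohort$outcome_t2dm <- 0L
  aric <- load_published_models()$ARIC
  expect_warning(ctx <- estimate_context(cohort, aric), "no events")
  expect_equal(ctx$s_m, 1)
  expect_equal(recalibrate(aric, ctx, cohort)$probability,
               rep(0, nrow(cohort)))
  expect_error(estimate_context(cohort[0, ], aric), "empty")
})

test_that("recalibration ignores the external intercept entirely", {
  cohort <- small_cohort(n = 1000, seed = 64)
  aric <- load_published_models()$ARIC
  ctx <- estimate_context(cohort, aric)
  p1 <- recalibrate(aric, ctx, cohort)$probability
  shifted <- aric
  shifted$intercept <- 37.4
  p2 <- recalibrate(shifted, estimate_context(cohort, shifted), cohort)
  expect_equal(p2$probability, p1)
})

test_that("two-step procedure removes race terms and recalibrates per group", {
  aric <- load_published_models()$ARIC
  cohort <- small_cohort(n = 1500, seed = 65)
  ts <- two_step_race_recalibration(aric, cohort)
  expect_equal(ts$id, cohort$id)
  expect_setequal(unique(ts$stratum), c("Chinese", "Malay", "Indian"))
  # within each group, ranking equals the ranking of the centred score
  for (g in unique(ts$stratum)) {
    i <- ts$stratum == g
    expect_equal(order(ts$probability[i]), order(ts$linear_predictor[i]))
  }
  # a single-ethnicity cohort reduces to plain race-free recalibration
  chin <- cohort[cohort$ethnicity == "Chinese", ]
  ts1 <- two_step_race_recalibration(aric, chin)
  plain <- recalibrate(drop_race_terms(aric),
                       estimate_context(chin, drop_race_terms(aric)), chin)
  expect_equal(ts1$probability, plain$probability)
  # no race term: error
  expect_error(two_step_race_recalibration(drop_race_terms(aric), cohort),
               "race term")
})

test_that("two-step recalibration recovers group-specific incidence", {
  # groups with different baseline risk, n = 5000 per group
  aric <- load_published_models()$ARIC
  cfg <- cohort_config(n = 10000,
                       ethnic_props = c(Chinese = 0.5, Malay = 0.5,
                                        Indian = 0))
  cohort <- generate_cohort(cfg, seed = 66)
  ts <- two_step_race_recalibration(aric, cohort,
                                    method = "intercept_matched")
  for (g in c("Chinese", "Malay")) {
    i <- cohort$ethnicity == g
    expect_lt(abs(mean(ts$probability[i]) - mean(cohort$outcome_t2dm[i])),
              0.01)
  }
})

test_that("age-stratified recalibration matches its contracts", {
  aric <- load_published_models()$ARIC
  cohort <- small_cohort(n = 1500, seed = 67)
  one_band <- stratified_recalibration_by_age(aric, cohort,
                                              breaks = c(18, 101))
  flat <- recalibrate(aric, estimate_context(cohort, aric), cohort)
  expect_equal(one_band$probability, flat$probability)
  expect_error(
    stratified_recalibration_by_age(aric, cohort, breaks = c(18, 101, 150)),
    "empty age band|cover")
})

test_that("per-band recalibration absorbs a birth-cohort effect", {
  # outcomes carry an extra old-age risk bump the linear age term of the
  # external model cannot represent
  aric <- load_published_models()$ARIC
  cfg <- cohort_config(n = 10000)
  cohort <- generate_cohort(cfg, seed = 68)
  truth <- attr(cohort, "outcome_model")
  X <- encode_subjects(cohort, truth)
  eta <- truth$intercept + drop(X %*% truth$beta) +
    1.0 * (cohort$age >= 50)
  set.seed(69)
  cohort$outcome_t2dm <- stats::rbinom(nrow(cohort), 1,
                                       stats::plogis(eta))
  ext <- truth
  flat <- recalibrate(ext, estimate_context(cohort, ext,
                                            method = "intercept_matched"),
                      cohort)
  banded <- stratified_recalibration_by_age(
    ext, cohort, breaks = c(18, 35, 50, 101),
    method = "intercept_matched")
  y <- cohort$outcome_t2dm
  hl_flat <- hosmer_lemeshow(flat$probability, y)$statistic
  hl_band <- hosmer_lemeshow(banded$probability, y)$statistic
  expect_lt(hl_band, hl_flat)
})
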