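test_that("logistic MLE satisfies closed-form identities", {
  cohort <- small_cohort(n = 1000, seed = 11)
  # intercept-only fit recovers logit of the event fraction
  cohort$outcome_t2dm <- rep(c(1, 0), c(300, 700))
  m0 <- fit_local_model(cohort, list(), name = "null")
  expect_equal(m0$intercept, stats::qlogis(0.3), tolerance = 1e-8)
  # calibration-in-the-large of the MLE: mean fitted = event rate
  cohort <- small_cohort(n = 1500, seed = 12)
  fit <- fit_local_model(cohort, load_published_models()$ARIC)
  expect_lt(abs(mean(fit$fit$fitted) - mean(cohort$outcome_t2dm)), 1e-8)
  # AIC identity and refit determinism
  expect_equal(fit$fit$aic,
               2 * (length(fit$beta) + 1) - 2 * fit$fit$loglik)
  refit <- fit_local_model(cohort, load_published_models()$ARIC)
  expect_equal(refit$fit$aic, fit$fit$aic, tolerance = 1e-6)
  expect_equal(refit$beta, fit$beta)
})

test_that("local fit recovers generating coefficients at n = 5000", {
  cohort <- generate_cohort(cohort_config(n = 5000), seed = 21)
  truth <- attr(cohort, "outcome_model")
  fit <- fit_local_model(cohort, truth)
  z <- abs(fit$beta - truth$beta) / fit$fit$se
  expect_true(all(z < 3))
  zi <- abs(fit$intercept - truth$intercept) / fit$fit$se_intercept
  expect_lt(zi, 3)
})

test_that("degenerate designs raise explicit errors", {
  cohort <- small_cohort(n = 200, seed = 31)
  dup <- list(term_spec("bmi", "bmi", "linear"),
              term_spec("bmi2", "bmi", "linear"))
  expect_error(fit_local_model(cohort, dup), "rank deficient.*bmi")
  cohort$outcome_t2dm <- 0
  expect_error(fit_local_model(cohort, fpg_only_terms()),
               "at least one event")
  # perfectly separated outcome
  sep <- small_cohort(n = 200, seed = 32)
  sep$outcome_t2dm <- as.integer(sep$fpg > stats::median(sep$fpg))
  expect_error(suppressWarnings(fit_local_model(sep, fpg_only_terms())),
               "separation")
})

test_that("race coding is chosen by AIC and reports both AICs", {
  mods <- load_published_models()
  # equal Malay/Indian log-odds: the combined dummy should win most runs
  wins <- 0
  reps <- 40
  for (i in seq_len(reps)) {
    cohort <- generate_cohort(cohort_config(n = 1200), seed = 300 + i)
    ch <- choose_race_coding(cohort, mods$ARIC)
    expect_true(all(is.finite(ch$aic)))
    expect_equal(ch$coding,
                 c("combined", "separate")[which.min(ch$aic)])
    if (ch$coding == "combined") wins <- wins + 1
  }
  expect_gt(wins / reps, 0.5)
})

test_that("strongly different Malay and Indian effects select two dummies", {
  base <- load_published_models()$ARIC
  idx <- which(names(base$beta) == "ethnicity")
  sep_terms <- append(
    base$terms[-idx],
    list(term_spec("malay", "ethnicity", "level", level = "Malay"),
         term_spec("indian", "ethnicity", "level", level = "Indian")),
    after = idx - 1)
  gen <- risk_model("gen", sep_terms,
                    beta = unname(c(base$beta[-idx][seq_len(idx - 1)],
                                    0.1, 2.4,
                                    base$beta[-idx][-seq_len(idx - 1)])),
                    provenance = "published")
  cohort <- generate_cohort(
    cohort_config(n = 6000, outcome_model = gen), seed = 77)
  ch <- choose_race_coding(cohort, base)
  expect_equal(ch$coding, "separate")
  expect_lt(ch$aic[["separate"]], ch$aic[["combined"]])
})

test_that("interaction screen holds its size and finds real interactions", {
  terms <- list(term_spec("age", "age", "linear"),
                term_spec("fpg", "fpg", "linear", unit = "mg/dl"),
                term_spec("ethnicity", "ethnicity", "non_chinese"))
  # type-I error of the per-term LRT over null replicates; outcomes are
  # generated from exactly the base terms so the null model is true
  null_model <- risk_model("null-gen", terms, beta = c(0.03, 0.05, 0.5))
  kept <- 0
  tested <- 0
  for (i in seq_len(500)) {
    cohort <- generate_cohort(
      cohort_config(n = 400, target_incidence = 0.15,
                    outcome_model = null_model), seed = 4000 + i)
    scr <- screen_ethnicity_interactions(cohort, terms)
    ok <- !is.na(scr$kept)
    kept <- kept + sum(scr$kept[ok])
    tested <- tested + sum(ok)
  }
  expect_gt(kept / tested, 0.03)
  expect_lt(kept / tested, 0.08)
  # a strong FPG-by-ethnicity interaction is detected at n = 5000
  cohort <- generate_cohort(cohort_config(n = 5000), seed = 555)
  X <- encode_subjects(cohort, terms)
  eta <- -9 + 0.06 * X[, "fpg"] + 0.02 * X[, "age"] +
    X[, "ethnicity"] * (0.05 * X[, "fpg"] - 4.5)
  set.seed(556)
  cohort$outcome_t2dm <- stats::rbinom(nrow(cohort), 1,
                                       stats::plogis(eta))
  scr <- screen_ethnicity_interactions(cohort, terms)
  expect_true(scr$kept[scr$term == "fpg"])
  expect_true(all(scr$lrt >= 0, na.rm = TRUE))
})

test_that("coefficient comparison flags published values outside the CI", {
  terms <- list(term_spec("fpg", "fpg", "linear", unit = "mg/dl"),
                term_spec("ethnicity", "ethnicity", "non_chinese"))
  local <- risk_model(
    "loc", terms, beta = c(0.120, 0.677), intercept = -5,
    provenance = "local",
    fit = list(ci_lower = c(fpg = 0.090, ethnicity = 0.214),
               ci_upper = c(fpg = 0.149, ethnicity = 1.140)))
  published <- risk_model("pub", terms, beta = c(0.0880, 0.4433))
  cmp <- compare_coefficients(local, published)
  expect_true(cmp$outside_ci[cmp$term == "fpg"])        # 0.0880 below CI
  expect_false(cmp$outside_ci[cmp$term == "ethnicity"]) # 0.4433 inside
  # a published value equal to the local point estimate is never flagged
  pub2 <- risk_model("pub2", terms, beta = c(0.120, 0.677))
  expect_false(any(compare_coefficients(local, pub2)$outside_ci))
  # unmatched term sets are an error
  pub3 <- risk_model("pub3", terms[1], beta = 0.1)
  expect_error(compare_coefficients(local, pub3), "ethnicity")
})
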