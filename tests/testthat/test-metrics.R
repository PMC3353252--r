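test_that("AUC equals the all-pairs Mann-Whitney count", {
  expect_equal(auc(c(0.8, 0.6, 0.7, 0.2), c(1, 1, 0, 0))$auc, 0.75)
  expect_equal(auc(c(5, 6, 1, 2), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(auc(rep(0.3, 10), rep(c(1, 0), 5))$auc, 0.5)
  set.seed(101)
  for (i in 1:200) {
    n <- sample(10:50, 1)
    y <- c(1, 0, stats::rbinom(n - 2, 1, 0.4))
    s <- round(stats::runif(n), sample(1:3, 1))  # force some ties
    expect_equal(auc(s, y)$auc, brute_auc(s, y))
  }
  expect_error(auc(1:5, rep(1, 5)), "both")
})

test_that("AUC is invariant to monotone score transforms", {
  set.seed(102)
  s <- stats::rnorm(100)
  y <- stats::rbinom(100, 1, stats::plogis(s))
  expect_equal(auc(s, y)$auc, auc(stats::plogis(s), y)$auc)
  expect_equal(auc(s, y)$auc, auc(rank(s), y)$auc)
})

test_that("DeLong machinery agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(103)
  n <- 300
  x <- stats::rnorm(n)
  y <- stats::rbinom(n, 1, stats::plogis(-1 + x))
  s1 <- x + stats::rnorm(n, 0, 0.8)
  s2 <- x + stats::rnorm(n, 0, 1.2)
  a <- auc(s1, y)
  r <- pROC::roc(y, s1, quiet = TRUE, direction = "<")
  expect_equal(a$auc, as.numeric(pROC::auc(r)))
  expect_equal(a$ci, as.numeric(pROC::ci.auc(r, method = "delong"))[c(1, 3)],
               tolerance = 1e-8)
  d <- delong_compare(s1, s2, y)
  rt <- pROC::roc.test(pROC::roc(y, s1, quiet = TRUE, direction = "<"),
                       pROC::roc(y, s2, quiet = TRUE, direction = "<"),
                       method = "delong")
  expect_equal(d$p, as.numeric(rt$p.value), tolerance = 1e-8)
  expect_equal(d$z, as.numeric(rt$statistic), tolerance = 1e-8)
})

test_that("DeLong self-comparison and consistency with auc()", {
  set.seed(104)
  s <- stats::runif(200)
  y <- stats::rbinom(200, 1, s)
  d <- delong_compare(s, s, y)
  expect_equal(d$diff, 0)
  expect_equal(d$p, 1)
  s2 <- stats::runif(200)
  d2 <- delong_compare(s, s2, y)
  expect_equal(d2$auc1, auc(s, y)$auc)
  expect_equal(d2$auc2, auc(s2, y)$auc)
  expect_error(delong_compare(s, s2[-1], y), "equal length")
})

test_that("DeLong test holds its size under the null", {
  # two equally informative noisy copies of the same signal
  set.seed(105)
  rej <- 0
  for (i in 1:500) {
    x <- stats::rnorm(150)
    y <- stats::rbinom(150, 1, stats::plogis(-1 + 1.2 * x))
    s1 <- x + stats::rnorm(150)
    s2 <- x + stats::rnorm(150)
    if (delong_compare(s1, s2, y)$p < 0.05) rej <- rej + 1
  }
  expect_gt(rej / 500, 0.03)
  expect_lt(rej / 500, 0.08)
})

test_that("NRI components equal brute-force reclassification counts", {
  set.seed(106)
  for (i in 1:200) {
    n <- sample(10:50, 1)
    y <- c(1, 0, stats::rbinom(n - 2, 1, 0.3))
    p_old <- round(stats::runif(n), 2)
    p_new <- pmin(pmax(p_old + stats::rnorm(n, 0, 0.15), 0), 1)
    got <- nri(p_new, p_old, y)
    want <- brute_nri(p_new, p_old, y)
    expect_equal(got$nri_events, want$events)
    expect_equal(got$nri_nonevents, want$nonevents)
    expect_equal(got$nri_total, want$total)
  }
})

test_that("NRI respects its category bounds and edge cases", {
  # probability exactly at a bound stays in the lower category
  y <- c(1, 0)
  r <- nri(c(0.10, 0.101), c(0.05, 0.05), y)
  expect_equal(r$event_up, 0)     # 0.10 is still category 1
  expect_equal(r$nonevent_up, 1)  # 0.101 crossed into category 2
  # identical predictions: all components zero
  p <- stats::runif(50)
  y2 <- rep(c(1, 0), 25)
  r0 <- nri(p, p, y2)
  expect_equal(r0$nri_events, 0)
  expect_equal(r0$nri_nonevents, 0)
  expect_equal(r0$nri_total, 0)
  expect_error(nri(c(1.2, 0.5), c(0.1, 0.2), c(1, 0)), "\\[0, 1\\]")
  # invariants of the decomposition
  r1 <- nri_from_counts(32, 21, 110, 76, 110, 1291)
  expect_equal(r1$nri_total, r1$nri_events + r1$nri_nonevents)
})

test_that("Hosmer-Lemeshow statistic matches hand evaluation", {
  # two groups of 10: E = (2, 5), O = (4, 5)
  p <- c(rep(0.2, 10), rep(0.5, 10))
  y <- c(rep(1, 4), rep(0, 6), rep(1, 5), rep(0, 5))
  h <- hosmer_lemeshow(p, y, groups = 2)
  expect_equal(h$statistic, 4 / (2 * 0.8))
  expect_equal(h$df, 0)
  expect_equal(h$table$observed, c(4, 5))
  expect_equal(h$table$expected, c(2, 5))
  # perfectly matching groups give a zero statistic
  h0 <- hosmer_lemeshow(c(rep(0.2, 10), rep(0.6, 10)),
                        c(rep(1, 2), rep(0, 8), rep(1, 6), rep(0, 4)),
                        groups = 2)
  expect_equal(h0$statistic, 0)
})

test_that("Hosmer-Lemeshow grouping is deterministic and order-invariant", {
  set.seed(107)
  p <- stats::runif(500, 0, 0.4)
  y <- stats::rbinom(500, 1, p)
  h1 <- hosmer_lemeshow(p, y)
  expect_equal(h1$df, 3)
  expect_equal(sum(h1$table$n), 500)
  # permuting subjects (with distinct probabilities) changes nothing
  i <- sample(500)
  h2 <- hosmer_lemeshow(p[i], y[i])
  expect_equal(h2$statistic, h1$statistic)
})

test_that("predicted incidence is the mean probability in percent", {
  expect_equal(predicted_incidence(rep(0.078, 10)), 7.8)
  expect_error(predicted_incidence(numeric(0)), "non-empty")
  cohort <- small_cohort(n = 600, seed = 108)
  fit <- fit_local_model(cohort, fpg_only_terms())
  expect_equal(predicted_incidence(fit$fit$fitted),
               100 * mean(cohort$outcome_t2dm))
})

test_that("validation_report assembles AUC and calibration tables", {
  cohort <- small_cohort(n = 600, seed = 109)
  y <- cohort$outcome_t2dm
  aric <- load_published_models()$ARIC
  rc <- recalibrate(aric, estimate_context(cohort, aric), cohort)
  lp <- as.numeric(linear_predictor(aric, encode_subjects(cohort, aric),
                                    rank_only = TRUE))
  rep <- validation_report(
    list(recal = rc$probability, rank = lp), y,
    pairs = list(c("recal", "rank")))
  expect_equal(rep$auc$model, c("recal", "rank"))
  # same ordering, same AUC
  expect_equal(rep$auc$auc[1], rep$auc$auc[2])
  expect_equal(rep$comparisons$diff, 0)
  expect_equal(rep$calibration$model, "recal")
})
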