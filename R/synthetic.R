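.default_means <- c(age = 36.14, bmi = 22.80, fpg = 5.35, hdl = 1.26,
                    sbp = 114.45, waist = 78.0, height = 163.0,
                    triglyceride = 1.35)
.default_sds <- c(age = 10.84, bmi = 3.85, fpg = 0.44, hdl = 0.31,
                  sbp = 14.58, waist = 9.5, height = 8.0,
                  triglyceride = 0.70)
.lower_bounds <- c(age = 18, bmi = 13, fpg = 3.0, hdl = 0.4, sbp = 70,
                   waist = 50, height = 130, triglyceride = 0.3)

.default_corr <- function(fields) {
  k <- length(fields)
  R <- matrix(0.1, k, k, dimnames = list(fields, fields))
  diag(R) <- 1
  set_r <- function(a, b, r) {
    if (a %in% fields && b %in% fields) {
      R[a, b] <<- r
      R[b, a] <<- r
    }
  }
  set_r("bmi", "waist", 0.8)
  set_r("fpg", "bmi", 0.3)
  set_r("sbp", "age", 0.35)
  R
}

#' Configuration for the synthetic cohort generator
#'
#' Describes a multi-ethnic Asian health-survey population: ethnic
#' mix (60% Chinese, 20% Malay, 20% Indian by default), covariate
#' means/SDs matching the survey's baseline marginals (age
#' 36.14 +/- 10.84 y, BMI 22.80 +/- 3.85, FPG 5.35 +/- 0.44 mmol/L,
#' HDL 1.26 +/- 0.31 mmol/L, SBP 114.45 +/- 14.58 mmHg, family-history
#' prevalence 35.5%), a covariate correlation matrix, and an outcome
#' model whose intercept is tuned so the realised expected incidence
#' equals `target_incidence` (7.8% by default, the observed cumulative
#' incidence over the follow-up period).
#'
#' @param n Cohort size.
#' @param ethnic_props Named proportions for Chinese/Malay/Indian;
#'   must sum to 1.
#' @param prop_male Proportion of males.
#' @param means,sds Named means/SDs of the continuous covariates
#'   (cohort units); entries override the defaults.
#' @param ethnic_mean_offsets Named list (by ethnicity) of named mean
#'   offsets, e.g. `list(Malay = c(bmi = 0.8))`; defaults give Malay
#'   and Indian strata slightly higher adiposity and fasting glucose.
#' @param famhist_prev Prevalence of positive family history.
#' @param corr Correlation matrix of the continuous covariates (must be
#'   positive definite); defaults: BMI-waist 0.8, FPG-BMI 0.3, SBP-age
#'   0.35, all other pairs 0.1.
#' @param outcome_model [risk_model()] generating the outcome; default
#'   is the published ARIC coefficient vector.
#' @param target_incidence Expected outcome incidence in (0, 1).
#' @param two_hpg_sd Residual SD of the 2-hour glucose around its
#'   FPG-linked mean (controls the FPG/2hPG correlation).
#' @param eligible_only If `TRUE` (default), baseline glucose values
#'   are truncated below the diagnostic cutoffs so every subject is
#'   eligible (the generator emulates a post-exclusion cohort); if
#'   `FALSE`, a small fraction of baseline-diabetic subjects is
#'   produced so the eligibility filter has work to do.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n = 1401,
                          ethnic_props = c(Chinese = 0.60, Malay = 0.20,
                                           Indian = 0.20),
                          prop_male = 0.478,
                          means = NULL, sds = NULL,
                          ethnic_mean_offsets = list(
                            Malay = c(bmi = 0.8, fpg = 0.04),
                            Indian = c(bmi = 0.5, fpg = 0.07)),
                          famhist_prev = 0.355,
                          corr = NULL,
                          outcome_model = NULL,
                          target_incidence = 0.078,
                          two_hpg_sd = 0.75,
                          eligible_only = TRUE) {
  mu <- .default_means
  sd <- .default_sds
  if (!is.null(means)) mu[names(means)] <- means
  if (!is.null(sds)) sd[names(sds)] <- sds
  if (any(sd <= 0)) stop("all SDs must be positive")
  if (abs(sum(ethnic_props) - 1) > 1e-8)
    stop("ethnic proportions must sum to 1")
  if (target_incidence <= 0 || target_incidence >= 1)
    stop("target incidence must lie in (0, 1)")
  R <- if (is.null(corr)) .default_corr(names(mu)) else corr
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("correlation matrix must be positive definite")
  if (is.null(outcome_model))
    outcome_model <- load_published_models()$ARIC
  structure(list(n = n, ethnic_props = ethnic_props,
                 prop_male = prop_male, means = mu, sds = sd,
                 ethnic_mean_offsets = ethnic_mean_offsets,
                 famhist_prev = famhist_prev, corr = R,
                 outcome_model = outcome_model,
                 target_incidence = target_incidence,
                 two_hpg_sd = two_hpg_sd,
                 eligible_only = eligible_only),
            class = "cohort_config")
}

# Tune the outcome model intercept so mean plogis(c + score) hits the
# target incidence on the realised covariates.
.tune_intercept <- function(score, target) {
  f <- function(c0) mean(stats::plogis(c0 + score)) - target
  lo <- -50
  hi <- 20
  if (f(lo) > 0 || f(hi) < 0)
    stop("target incidence infeasible for the outcome model")
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Generate a synthetic cohort
#'
#' Draws a cohort from a [cohort_config()]: ethnicity and sex
#' multinomially, continuous covariates from a truncated multivariate
#' normal on the configured scales (heights sex-shifted), family
#' history by prevalence, 2-hour glucose as FPG-linked noise, auxiliary
#' imputer variables (LDL, hip, waist-hip ratio, creatinine, insulin
#' resistance), and the diabetes outcome as a Bernoulli draw from the
#' configured logistic outcome model with its intercept tuned by
#' root-finding so the expected incidence equals the target.  Follow-up
#' glucose and physician-diagnosis flags are generated consistently
#' with the drawn outcome.  The generating model (with its tuned
#' intercept) is attached as attribute `"outcome_model"`.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; the same seed reproduces the cohort
#'   exactly.
#' @param intercept Optional fixed outcome-model intercept, bypassing
#'   the tuning (used to build populations with a shifted baseline
#'   risk).
#' @return A validated cohort data frame.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 500), seed = 1)
#' mean(cohort$outcome_t2dm)
generate_cohort <- function(config = cohort_config(), seed = 1,
                            intercept = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  n <- config$n
  eth <- sample(names(config$ethnic_props), n, replace = TRUE,
                prob = config$ethnic_props)
  sex <- sample(c("male", "female"), n, replace = TRUE,
                prob = c(config$prop_male, 1 - config$prop_male))
  fields <- names(config$means)
  Sigma <- diag(config$sds[fields]) %*% config$corr[fields, fields] %*%
    diag(config$sds[fields])
  Z <- MASS::mvrnorm(n, mu = rep(0, length(fields)), Sigma = Sigma)
  colnames(Z) <- fields
  X <- sweep(Z, 2, config$means[fields], "+")
  for (e in names(config$ethnic_mean_offsets)) {
    off <- config$ethnic_mean_offsets[[e]]
    for (f in intersect(names(off), fields))
      X[eth == e, f] <- X[eth == e, f] + off[[f]]
  }
  if ("height" %in% fields) {
    X[sex == "male", "height"] <- X[sex == "male", "height"] + 6
    X[sex == "female", "height"] <- X[sex == "female", "height"] - 6
  }
  for (f in fields)
    X[, f] <- pmax(X[, f], .lower_bounds[[f]])
  X[, "age"] <- pmin(X[, "age"], 100)
  cohort <- data.frame(
    id = sprintf("S%06d", seq_len(n)),
    age = X[, "age"], sex = sex, ethnicity = eth,
    fpg = X[, "fpg"], sbp = X[, "sbp"], hdl = X[, "hdl"],
    triglyceride = X[, "triglyceride"], bmi = X[, "bmi"],
    waist = X[, "waist"], height = X[, "height"],
    stringsAsFactors = FALSE)
  cohort$two_hpg <- pmax(0.6 + 1.0 * cohort$fpg +
                           stats::rnorm(n, 0, config$two_hpg_sd), 1.0)
  cohort$family_history_t2dm <- stats::rbinom(n, 1, config$famhist_prev)
  # auxiliary imputer-only variables
  cohort$ldl <- pmax(3.2 + 0.4 * scale(cohort$triglyceride)[, 1] +
                       stats::rnorm(n, 0, 0.8), 0.5)
  cohort$hip <- pmax(cohort$waist + stats::rnorm(n, 16, 4), 55)
  cohort$waist_hip_ratio <- cohort$waist / cohort$hip
  cohort$creatinine <- pmax(stats::rnorm(n, 75, 15), 30)
  cohort$insulin_resistance <- pmax(1.6 + 0.15 * (cohort$bmi - 22.8) +
                                      stats::rnorm(n, 0, 0.8), 0.2)
  if (config$eligible_only) {
    cohort$fpg <- pmin(cohort$fpg, 6.99)
    cohort$two_hpg <- pmin(cohort$two_hpg, 11.05)
    cohort$diagnosed_t2dm <- 0
  } else {
    cohort$diagnosed_t2dm <- stats::rbinom(n, 1, 0.03)
  }
  model <- config$outcome_model
  score <- drop(encode_subjects(cohort, model) %*% model$beta)
  c0 <- if (is.null(intercept)) .tune_intercept(score,
                                                config$target_incidence)
        else intercept
  p <- stats::plogis(c0 + score)
  event <- stats::rbinom(n, 1, p)
  # follow-up measurements consistent with the drawn outcome
  dx <- integer(n)
  fpg_fu <- numeric(n)
  is_ev <- event == 1
  dx[is_ev] <- stats::rbinom(sum(is_ev), 1, 0.15)
  fpg_fu[is_ev] <- ifelse(dx[is_ev] == 1,
                          stats::rnorm(sum(is_ev), 6.2, 0.5),
                          7.0 + abs(stats::rnorm(sum(is_ev), 0.8, 0.9)))
  fpg_fu[!is_ev] <- pmin(stats::rnorm(sum(!is_ev),
                                      5.5 + 0.3 * (cohort$fpg[!is_ev] - 5.35),
                                      0.5), 6.95)
  fpg_fu <- pmax(fpg_fu, 3.0)
  cohort$fpg_followup <- fpg_fu
  cohort$physician_dx_followup <- dx
  cohort$outcome_t2dm <- define_outcome(fpg_fu, dx)
  stopifnot(all(cohort$outcome_t2dm == event))
  validate_cohort(cohort)
  truth <- risk_model(model$name, model$terms, unname(model$beta),
                      intercept = c0, provenance = model$provenance)
  attr(cohort, "outcome_model") <- truth
  attr(cohort, "true_probability") <- p
  cohort
}

#' Generate an external derivation population
#'
#' Draws a population that differs from the base configuration by
#' shifted covariate means and a shifted outcome-model intercept —
#' the situation in which an externally derived function is
#' transported to a local population with different risk-factor levels
#' and baseline incidence.  The returned generating model (shifted
#' intercept, same coefficient vector) is the ground truth for
#' recalibration experiments: applied as-is to a cohort drawn from the
#' unshifted config it is miscalibrated, while its coefficient vector
#' is correct.
#'
#' @param config Base [cohort_config()].
#' @param intercept_shift Added to the intercept tuned for the base
#'   target incidence (e.g. `log(2)` doubles the outcome odds at fixed
#'   covariates).
#' @param mean_shifts Named numeric vector of covariate mean shifts.
#' @param seed Integer seed.
#' @return List with `cohort` (drawn from the shifted population) and
#'   `model` (the generating [risk_model()] with known intercept).
#' @export
generate_external_population <- function(config = cohort_config(),
                                         intercept_shift = 0,
                                         mean_shifts = NULL, seed = 1) {
  cfg <- config
  if (!is.null(mean_shifts)) {
    bad <- setdiff(names(mean_shifts), names(cfg$means))
    if (length(bad) > 0)
      stop("unknown covariate(s) in mean_shifts: ",
           paste(bad, collapse = ", "))
    cfg$means[names(mean_shifts)] <-
      cfg$means[names(mean_shifts)] + mean_shifts
  }
  base <- generate_cohort(config, seed = seed)
  c0 <- attr(base, "outcome_model")$intercept
  cohort <- generate_cohort(cfg, seed = seed + 1,
                            intercept = c0 + intercept_shift)
  list(cohort = cohort, model = attr(cohort, "outcome_model"))
}

#' Apply a missing-at-random dropout mechanism
#'
#' Deletes follow-up measurements (follow-up glucose, the follow-up
#' diagnosis flag and hence the outcome) with a probability given by a
#' logistic model on observed baseline fields only — the mechanism is
#' MAR by construction and is rejected if it references any follow-up
#' field.  The true deleted values are kept in attribute
#' `"true_followup"` so recovery experiments have an oracle.
#'
#' @param cohort Cohort data frame.
#' @param mechanism Named numeric vector of logistic coefficients; the
#'   `"(Intercept)"` entry is the intercept, all other names must be
#'   baseline cohort fields (`sex`/`ethnicity` enter as female and
#'   non-Chinese indicators).
#' @param seed Integer seed.
#' @return The cohort with `fpg_followup`, `physician_dx_followup` and
#'   `outcome_t2dm` set to `NA` for dropouts; attributes
#'   `"true_followup"` (deleted rows' original values) and
#'   `"dropout_probability"`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 300), seed = 1)
#' dropped <- apply_mar_dropout(cohort,
#'   c(`(Intercept)` = stats::qlogis(0.4)), seed = 2)
#' mean(is.na(dropped$fpg_followup))
apply_mar_dropout <- function(cohort, mechanism, seed = 1) {
  validate_cohort(cohort)
  vars <- setdiff(names(mechanism), "(Intercept)")
  followup_fields <- c("fpg_followup", "physician_dx_followup",
                       "outcome_t2dm")
  if (any(vars %in% followup_fields))
    stop("dropout mechanism may only reference baseline fields ",
         "(a follow-up-dependent mechanism would be missing not at random)")
  absent <- setdiff(vars, names(cohort))
  if (length(absent) > 0)
    stop("mechanism references unknown field(s): ",
         paste(absent, collapse = ", "))
  eta <- rep(if ("(Intercept)" %in% names(mechanism))
    mechanism[["(Intercept)"]] else 0, nrow(cohort))
  for (v in vars) {
    x <- switch(v,
                sex = as.numeric(cohort$sex == "female"),
                ethnicity = as.numeric(cohort$ethnicity != "Chinese"),
                as.numeric(cohort[[v]]))
    eta <- eta + mechanism[[v]] * x
  }
  p <- stats::plogis(eta)
  set.seed(seed)
  drop_i <- stats::rbinom(nrow(cohort), 1, p) == 1
  truth <- cohort[drop_i, c("id", followup_fields), drop = FALSE]
  out <- cohort
  out$fpg_followup[drop_i] <- NA_real_
  out$physician_dx_followup[drop_i] <- NA_integer_
  out$outcome_t2dm[drop_i] <- NA_integer_
  attr(out, "true_followup") <- truth
  attr(out, "dropout_probability") <- p
  attr(out, "outcome_model") <- attr(cohort, "outcome_model")
  out
}
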