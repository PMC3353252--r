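.outcome_vector <- function(cohort) {
  if (!"outcome_t2dm" %in% names(cohort))
    stop("cohort has no 'outcome_t2dm' column; derive it with define_outcome()")
  y <- cohort$outcome_t2dm
  if (anyNA(y))
    stop("outcome_t2dm contains missing values; filter or impute first ",
         "(e.g. fcs_impute())")
  y
}

#' Fit a local logistic risk model by maximum likelihood
#'
#' Estimates the local version of a predictive function: a logistic
#' regression with the given term specification, fitted to the cohort's
#' observed outcomes by iteratively reweighted least squares.  Returns a
#' `risk_model` with provenance `"local"` carrying the MLE coefficients,
#' intercept, Wald standard errors and 95% confidence intervals,
#' log-likelihood and AIC (`2k - 2 logL`).
#'
#' @param cohort Cohort data frame with complete covariates for the
#'   terms and a non-missing `outcome_t2dm` column.
#' @param terms List of [term_spec()]s (or a [risk_model()] whose terms
#'   are reused).
#' @param name Name for the fitted model.
#' @param factors Unit conversion factors.
#' @return A [risk_model()] with `fit` metadata.
#' @export
fit_local_model <- function(cohort, terms, name = "local",
                            factors = unit_conversion_factors()) {
  if (inherits(terms, "risk_model")) {
    if (identical(name, "local")) name <- paste0(terms$name, "-local")
    terms <- terms$terms
  }
  y <- .outcome_vector(cohort)
  if (sum(y) < 1 || sum(1 - y) < 1)
    stop("logistic fit needs at least one event and one non-event")
  X <- encode_subjects(cohort, terms, factors)
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    dropped <- c("(Intercept)", colnames(X))[-qrX$pivot[seq_len(qrX$rank)]]
    stop("design matrix is rank deficient; offending term(s): ",
         paste(dropped, collapse = ", "))
  }
  dat <- data.frame(.y = y, X, check.names = FALSE)
  fit <- stats::glm(.y ~ ., data = dat, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-10,
                                                 maxit = 100))
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  perfect <- max(abs(y - stats::fitted(fit))) < 1e-6
  if (!fit$converged || perfect) {
    scaled <- abs(co[-1]) * apply(X, 2, stats::sd)
    off <- colnames(X)[!is.na(scaled) & scaled > 10]
    stop("logistic fit did not converge (possible separation); ",
         "offending term(s): ",
         paste(if (length(off)) off else colnames(X), collapse = ", "))
  }
  beta <- co[-1]
  se_b <- se[-1]
  ll <- as.numeric(stats::logLik(fit))
  k <- length(co)
  risk_model(
    name = name, terms = terms, beta = unname(beta),
    intercept = unname(co[1]), provenance = "local",
    fit = list(
      loglik = ll, aic = 2 * k - 2 * ll,
      se = stats::setNames(se_b, names(beta)),
      se_intercept = unname(se[1]),
      ci_lower = stats::setNames(beta - 1.96 * se_b, names(beta)),
      ci_upper = stats::setNames(beta + 1.96 * se_b, names(beta)),
      n = length(y), n_events = sum(y),
      fitted = unname(stats::fitted(fit))))
}

.race_term_index <- function(terms) {
  which(vapply(terms, function(t)
    t$encoding %in% c("non_chinese") ||
      (t$encoding == "level" && identical(t$field, "ethnicity")),
    TRUE))
}

#' Choose between one and two race dummy variables by AIC
#'
#' Fits the model twice: with a single combined non-Chinese dummy
#' (Malays and Asian Indians merged) and with separate Malay and Indian
#' dummies, both against the Chinese reference.  The coding with the
#' lower AIC is returned together with both AIC values.
#'
#' @param cohort Cohort data frame containing all three ethnic groups
#'   (if a group is absent the available coding is used with a
#'   warning).
#' @param terms Term list including one `non_chinese` race term (or a
#'   [risk_model()]).
#' @param name Base name for the fitted models.
#' @param factors Unit conversion factors.
#' @return List with `model` (the selected [risk_model()]), `coding`
#'   (`"combined"` or `"separate"`), and `aic` (named numeric vector
#'   with both AICs).
#' @export
choose_race_coding <- function(cohort, terms, name = "local",
                               factors = unit_conversion_factors()) {
  if (inherits(terms, "risk_model")) {
    if (identical(name, "local")) name <- paste0(terms$name, "-local")
    terms <- terms$terms
  }
  idx <- .race_term_index(terms)
  if (length(idx) != 1)
    stop("terms must contain exactly one combined race term")
  present <- unique(cohort$ethnicity)
  if (!all(c("Chinese", "Malay", "Indian") %in% present)) {
    warning("not all three ethnic groups present; keeping the combined ",
            "race coding")
    m <- fit_local_model(cohort, terms, name, factors)
    return(list(model = m, coding = "combined",
                aic = c(combined = m$fit$aic, separate = NA)))
  }
  sep_terms <- append(
    terms[-idx],
    list(term_spec("malay", "ethnicity", "level", level = "Malay"),
         term_spec("indian", "ethnicity", "level", level = "Indian")),
    after = idx - 1)
  m1 <- fit_local_model(cohort, terms, name, factors)
  m2 <- fit_local_model(cohort, sep_terms, paste0(name, "-2race"), factors)
  aic <- c(combined = m1$fit$aic, separate = m2$fit$aic)
  chosen <- if (aic["combined"] <= aic["separate"]) m1 else m2
  list(model = chosen,
       coding = if (aic["combined"] <= aic["separate"]) "combined"
                else "separate",
       aic = aic)
}

#' Screen covariate-by-ethnicity interactions by likelihood ratio test
#'
#' For each non-race term of the base model, fits the base model plus
#' the term's interaction with ethnicity (by default the dichotomous
#' non-Chinese dummy; optionally separate Malay/Indian dummies) and
#' computes the likelihood ratio statistic `2 (logL_full - logL_base)`
#' against a chi-squared reference with one (or two) degrees of freedom.
#' Terms with `p < alpha` are flagged as kept, mirroring the
#' between-population heterogeneity screen applied before accepting a
#' transported model structure.
#'
#' @param cohort Cohort data frame.
#' @param terms Base term list or [risk_model()].
#' @param alpha Significance level for keeping an interaction.
#' @param levels 2 for the non-Chinese dummy interaction, 3 for
#'   separate Malay/Indian interactions.
#' @param factors Unit conversion factors.
#' @return Data frame with one row per screened term: `term`, `lrt`,
#'   `df`, `p`, `kept` (`NA` when the interaction fit failed).
#' @export
screen_ethnicity_interactions <- function(cohort, terms, alpha = 0.05,
                                          levels = 2,
                                          factors = unit_conversion_factors()) {
  if (inherits(terms, "risk_model")) terms <- terms$terms
  stopifnot(levels %in% c(2, 3))
  y <- .outcome_vector(cohort)
  X <- encode_subjects(cohort, terms, factors)
  base <- stats::glm(y ~ X, family = stats::binomial(),
                     control = stats::glm.control(epsilon = 1e-10,
                                                  maxit = 100))
  ll0 <- as.numeric(stats::logLik(base))
  race <- .race_term_index(terms)
  eth2 <- as.numeric(cohort$ethnicity != "Chinese")
  eth3 <- cbind(malay = as.numeric(cohort$ethnicity == "Malay"),
                indian = as.numeric(cohort$ethnicity == "Indian"))
  rows <- lapply(setdiff(seq_along(terms), race), function(i) {
    Z <- if (levels == 2) X[, i] * eth2 else X[, i] * eth3
    res <- tryCatch({
      full <- stats::glm(y ~ X + Z, family = stats::binomial(),
                         control = stats::glm.control(epsilon = 1e-10,
                                                      maxit = 100))
      df <- length(stats::coef(full)) - length(stats::coef(base))
      if (!full$converged || df < 1) stop("interaction fit unstable")
      lrt <- max(0, 2 * (as.numeric(stats::logLik(full)) - ll0))
      p <- stats::pchisq(lrt, df, lower.tail = FALSE)
      data.frame(term = terms[[i]]$name, lrt = lrt, df = df, p = p,
                 kept = p < alpha)
    }, error = function(e)
      data.frame(term = terms[[i]]$name, lrt = NA_real_, df = NA_integer_,
                 p = NA_real_, kept = NA))
    res
  })
  do.call(rbind, rows)
}

#' Compare local coefficient estimates with published values
#'
#' For every shared term, reports the local estimate with its Wald 95%
#' confidence interval next to the published coefficient and flags terms
#' whose published value lies outside the local interval — the check
#' used to judge between-population homogeneity of effect sizes.
#'
#' @param local A local [risk_model()] with fit metadata.
#' @param published A published [risk_model()].
#' @return Data frame with columns `term`, `local_estimate`,
#'   `ci_lower`, `ci_upper`, `published`, `outside_ci`.
#' @export
compare_coefficients <- function(local, published) {
  if (is.null(local$fit))
    stop("'local' must be a fitted model with confidence intervals")
  lt <- names(local$beta)
  pt <- names(published$beta)
  unmatched <- c(setdiff(lt, pt), setdiff(pt, lt))
  if (length(unmatched) > 0)
    stop("models do not share the same terms; unmatched: ",
         paste(unique(unmatched), collapse = ", "))
  out <- data.frame(
    term = lt,
    local_estimate = unname(local$beta),
    ci_lower = unname(local$fit$ci_lower[lt]),
    ci_upper = unname(local$fit$ci_upper[lt]),
    published = unname(published$beta[lt]),
    stringsAsFactors = FALSE)
  out$outside_ci <- out$published < out$ci_lower |
    out$published > out$ci_upper
  out
}
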