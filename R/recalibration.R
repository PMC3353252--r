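#' Recalibration context: local means and event-free probability
#'
#' The recalibration of an externally developed logistic model needs
#' only two local quantities: the mean covariate vector `m` on the
#' model's encoding scale and the probability `S(m)` that a subject
#' with average risk factors remains event-free over the study period.
#' [estimate_context()] computes both from a local cohort, overall or
#' within strata.
#'
#' @param m Named numeric mean covariate vector (model encoding scale).
#' @param s_m Event-free probability in (0, 1].
#' @param method Estimation method used for `s_m`.
#' @param stratum Optional stratum label.
#' @param incidence Observed incidence in the stratum.
#' @param n Stratum size.
#' @return An object of class `recal_context`.
#' @export
recal_context <- function(m, s_m, method = "mean_plugin_incidence",
                          stratum = NA_character_, incidence = NA_real_,
                          n = NA_integer_) {
  if (!is.numeric(s_m) || length(s_m) != 1 || s_m <= 0 || s_m > 1)
    stop("s_m must be a single probability in (0, 1]")
  structure(list(m = m, s_m = s_m, method = method, stratum = stratum,
                 incidence = incidence, n = n),
            class = "recal_context")
}

#' @export
print.recal_context <- function(x, ...) {
  cat(sprintf("<recal_context>%s  S(m) = %.4f (%s), n = %s\n",
              if (is.na(x$stratum)) "" else paste0(" [", x$stratum, "]"),
              x$s_m, x$method,
              if (is.na(x$n)) "?" else x$n))
  print(round(x$m, 4))
  invisible(x)
}

.estimate_context_one <- function(cohort, model, method, stratum, factors) {
  if (nrow(cohort) == 0)
    stop("empty stratum", if (!is.na(stratum)) paste0(" '", stratum, "'"))
  y <- .outcome_vector(cohort)
  X <- encode_subjects(cohort, model, factors)
  m <- colMeans(X)
  inc <- mean(y)
  if (inc == 0) {
    warning("no events in stratum",
            if (!is.na(stratum)) paste0(" '", stratum, "'"),
            "; S(m) set to 1 and all recalibrated risks will be 0")
    return(recal_context(m, 1, method, stratum, inc, nrow(cohort)))
  }
  s_m <- switch(method,
    mean_plugin_incidence = 1 - inc,
    intercept_matched = {
      d <- drop(X %*% model$beta) - sum(m * model$beta)
      ed <- exp(d)
      # mean recalibrated probability is continuous and decreasing in s
      f <- function(s) mean(1 - exp(ed * log(s))) - inc
      stats::uniroot(f, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
    },
    stop("unknown s_m estimation method: ", method))
  recal_context(m, s_m, method, stratum, inc, nrow(cohort))
}

#' Estimate recalibration contexts from a local cohort
#'
#' Computes, overall or per stratum, the mean encoded covariate vector
#' and the event-free probability `S(m)` used by [recalibrate()].  Two
#' estimators of `S(m)` are available: `mean_plugin_incidence` (the
#' default) sets `S(m) = 1 - observed incidence`; `intercept_matched`
#' solves for the value of `S(m)` at which the mean recalibrated
#' probability equals the observed incidence (a monotone
#' one-dimensional root-find), i.e. exact calibration-in-the-large.
#'
#' @param cohort Cohort data frame with outcomes and complete
#'   covariates for the model's terms.
#' @param model A [risk_model()].
#' @param strata Optional: a vector of stratum labels (length
#'   `nrow(cohort)`) or the name of a cohort column to stratify by.
#' @param method `"mean_plugin_incidence"` or `"intercept_matched"`.
#' @param factors Unit conversion factors.
#' @return A single `recal_context`, or a named list of them (one per
#'   stratum) when `strata` is given.
#' @export
estimate_context <- function(cohort, model, strata = NULL,
                             method = c("mean_plugin_incidence",
                                        "intercept_matched"),
                             factors = unit_conversion_factors()) {
  method <- match.arg(method)
  if (is.null(strata))
    return(.estimate_context_one(cohort, model, method, NA_character_,
                                 factors))
  if (length(strata) == 1 && is.character(strata) &&
      strata %in% names(cohort))
    strata <- cohort[[strata]]
  stopifnot(length(strata) == nrow(cohort))
  levs <- unique(as.character(strata))
  out <- lapply(levs, function(s)
    .estimate_context_one(cohort[strata == s, , drop = FALSE], model,
                          method, s, factors))
  stats::setNames(out, levs)
}

#' Recalibrate an external model's predicted risks
#'
#' Applies the recalibration formula
#' `p(x) = 1 - S(m) ^ exp((x - m)' beta)`:
#' the external coefficient vector supplies the relative risk ordering
#' while the local mean covariates `m` and local event-free probability
#' `S(m)` anchor the absolute risk.  The external intercept is never
#' used, so recalibrated risks are invariant to it.
#'
#' @param model A [risk_model()] (published or local); only `beta` is
#'   used.
#' @param context A `recal_context` from [estimate_context()].
#' @param cohort Cohort data frame to predict for.
#' @param factors Unit conversion factors.
#' @return A `risk_prediction` data frame (`id`, `model`,
#'   `linear_predictor` = centred score `(x - m)' beta`, `probability`,
#'   `recalibrated = TRUE`, `stratum`).
#' @export
recalibrate <- function(model, context, cohort,
                        factors = unit_conversion_factors()) {
  stopifnot(inherits(context, "recal_context"))
  if (context$s_m <= 0) stop("degenerate context: S(m) must be > 0")
  X <- encode_subjects(cohort, model, factors)
  if (!identical(colnames(X), names(context$m)))
    stop("context means are not aligned with the model's terms")
  d <- drop(X %*% model$beta) - sum(context$m * model$beta)
  p <- 1 - exp(exp(d) * log(context$s_m))
  out <- data.frame(
    id = cohort$id, model = model$name, linear_predictor = d,
    probability = p, recalibrated = TRUE,
    stratum = context$stratum, stringsAsFactors = FALSE)
  class(out) <- c("risk_prediction", class(out))
  out
}

#' Drop race terms from a model
#'
#' Removes every ethnicity-derived term (the combined non-Chinese dummy
#' or separate ethnic-level dummies) and its coefficients.
#'
#' @param model A [risk_model()].
#' @return The model without race terms.
#' @export
drop_race_terms <- function(model) {
  idx <- .race_term_index(model$terms)
  if (length(idx) == 0) return(model)
  risk_model(name = model$name, terms = model$terms[-idx],
             beta = unname(model$beta[-idx]), intercept = model$intercept,
             provenance = model$provenance, fit = NULL)
}

.stratified_recalibration <- function(model, cohort, strata, method,
                                      factors) {
  contexts <- estimate_context(cohort, model, strata = strata,
                               method = method, factors = factors)
  preds <- lapply(names(contexts), function(s)
    recalibrate(model, contexts[[s]],
                cohort[as.character(strata) == s, , drop = FALSE],
                factors))
  out <- do.call(rbind, preds)
  out <- out[match(cohort$id, out$id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "contexts") <- contexts
  out
}

#' Two-step ethnicity-stratified recalibration
#'
#' The transportable part of a published model that contains race terms
#' is its non-race coefficients: step 1 removes the race terms, so that
#' within each ethnic group the risk ordering no longer depends on a
#' race coefficient estimated elsewhere; step 2 recalibrates the
#' race-free model separately within each ethnic group, so each group's
#' absolute risks are anchored on its own mean risk factors and
#' event-free probability.
#'
#' @param model A [risk_model()] containing at least one race term.
#' @param cohort Cohort data frame.
#' @param groups Ethnic grouping: a vector of labels or a cohort column
#'   name (default `"ethnicity"`).
#' @param method `S(m)` estimator, see [estimate_context()].
#' @param factors Unit conversion factors.
#' @return A `risk_prediction` data frame in cohort order with a
#'   `stratum` column; the per-group contexts are attached as attribute
#'   `"contexts"`.
#' @export
two_step_race_recalibration <- function(model, cohort,
                                        groups = "ethnicity",
                                        method = "mean_plugin_incidence",
                                        factors = unit_conversion_factors()) {
  if (length(.race_term_index(model$terms)) == 0)
    stop("model '", model$name, "' has no race term to remove")
  if (length(groups) == 1 && is.character(groups) &&
      groups %in% names(cohort))
    groups <- cohort[[groups]]
  stopifnot(length(groups) == nrow(cohort))
  .stratified_recalibration(drop_race_terms(model), cohort, groups,
                            method, factors)
}

#' Age-stratified recalibration
#'
#' Recalibrates within age bands, in the same manner as the
#' ethnicity-stratified procedure: each band gets its own mean
#' covariates and event-free probability, so a birth-cohort effect or a
#' nonlinear age effect that the external model's single age
#' coefficient cannot capture is absorbed into the per-band anchors.
#' The model's age term can optionally be removed first (analogous to
#' removing the race terms).
#'
#' @param model A [risk_model()].
#' @param cohort Cohort data frame.
#' @param breaks Age band boundaries passed to [cut()] (left-closed
#'   bands).
#' @param drop_age_term Remove linear age terms before recalibrating.
#' @param method `S(m)` estimator.
#' @param factors Unit conversion factors.
#' @return A `risk_prediction` data frame with a `stratum` column and
#'   attached `"contexts"`.
#' @export
stratified_recalibration_by_age <- function(model, cohort,
                                            breaks = c(18, 40, 60, 100),
                                            drop_age_term = FALSE,
                                            method = "mean_plugin_incidence",
                                            factors = unit_conversion_factors()) {
  bands <- cut(cohort$age, breaks = breaks, include.lowest = TRUE,
               right = FALSE)
  if (anyNA(bands))
    stop("age bands do not cover all subjects")
  if (any(table(factor(bands, levels = levels(bands))) == 0))
    stop("empty age band: ",
         paste(levels(bands)[table(bands) == 0], collapse = ", "))
  m <- model
  if (drop_age_term) {
    idx <- which(vapply(m$terms, function(t)
      identical(t$field, "age") && t$encoding == "linear", TRUE))
    if (length(idx) > 0)
      m <- risk_model(m$name, m$terms[-idx], unname(m$beta[-idx]),
                      m$intercept, m$provenance)
  }
  .stratified_recalibration(m, cohort, as.character(bands), method, factors)
}
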