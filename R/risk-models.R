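#' Specify one model term
#'
#' A term maps a subject-record field onto one column of the model's
#' covariate vector.  Supported encodings:
#' \describe{
#'   \item{linear}{the field value itself, converted to `unit` when the
#'     field is stored in mmol/L and the term is specified in mg/dl.}
#'   \item{binary}{a 0/1 field passed through unchanged.}
#'   \item{female}{1 for female subjects (male reference).}
#'   \item{non_chinese}{1 for Malay or Indian subjects (Chinese
#'     reference), the dichotomous race coding.}
#'   \item{level}{1 when `field` equals `level` (reference-coded factor
#'     dummy, e.g. separate Malay and Indian indicators).}
#'   \item{threshold}{1 when the field is `>= cutpoint` (direction
#'     `"ge"`) or `< cutpoint` (direction `"lt"`); `cutpoint_female`
#'     overrides the cutpoint for women (sex-specific lipid cutoffs).}
#'   \item{range}{1 when `lower <= field < upper` (e.g. impaired fasting
#'     glucose, or the overweight band of BMI).}
#' }
#' Cutpoints are on the field's native (cohort) scale.
#'
#' @param name Term name; must be a syntactic column name.
#' @param field Subject-record field the term reads.
#' @param encoding One of the encodings above.
#' @param unit Target unit for linear terms (`"mg/dl"` triggers
#'   mmol/L-to-mg/dl conversion for glucose/lipid fields).
#' @param cutpoint,cutpoint_female,direction Threshold parameters.
#' @param lower,upper Range parameters (lower inclusive, upper exclusive).
#' @param level Factor level for `level` encoding.
#' @return An object of class `term_spec`.
#' @export
term_spec <- function(name, field,
                      encoding = c("linear", "binary", "female",
                                   "non_chinese", "level", "threshold",
                                   "range"),
                      unit = NULL, cutpoint = NULL, cutpoint_female = NULL,
                      direction = c("ge", "lt"), lower = NULL, upper = NULL,
                      level = NULL) {
  encoding <- match.arg(encoding)
  direction <- match.arg(direction)
  if (encoding == "threshold" && is.null(cutpoint))
    stop("threshold encoding requires an explicit cutpoint for term '",
         name, "'")
  if (encoding == "range" && (is.null(lower) || is.null(upper)))
    stop("range encoding requires lower and upper bounds for term '",
         name, "'")
  if (encoding == "level" && is.null(level))
    stop("level encoding requires a level for term '", name, "'")
  structure(
    list(name = name, field = field, encoding = encoding, unit = unit,
         cutpoint = cutpoint, cutpoint_female = cutpoint_female,
         direction = direction, lower = lower, upper = upper,
         level = level),
    class = "term_spec")
}

#' Construct a logistic risk model
#'
#' A named logistic model: an ordered list of [term_spec()]s, one
#' coefficient per term, an optional intercept and a provenance tag.
#' Published models carry no fit metadata and typically an unknown
#' (`NA`) intercept — the original publications' constants are not
#' reproduced here — so absolute risks from published models flow
#' through [recalibrate()] (which never uses the intercept) or a
#' user-supplied intercept.
#'
#' @param name Model name (e.g. `"SAHS"`, `"ARIC"`, `"FRAM"`).
#' @param terms List of [term_spec()] objects.
#' @param beta Numeric coefficient vector, one per term.
#' @param intercept Intercept, or `NA` when unknown.
#' @param provenance `"published"` or `"local"`.
#' @param fit For local models, a list of fit metadata (log-likelihood,
#'   AIC, standard errors, confidence intervals); must be `NULL` for
#'   published models.
#' @return An object of class `risk_model`.
#' @export
risk_model <- function(name, terms, beta, intercept = NA_real_,
                       provenance = c("published", "local"), fit = NULL) {
  provenance <- match.arg(provenance)
  stopifnot(is.list(terms), all(vapply(terms, inherits, TRUE, "term_spec")))
  if (length(beta) != length(terms))
    stop("beta must have one coefficient per term (",
         length(beta), " vs ", length(terms), ")")
  if (provenance == "published" && !is.null(fit))
    stop("published models carry no fit metadata")
  names(beta) <- vapply(terms, `[[`, "", "name")
  structure(
    list(name = name, terms = terms, beta = beta,
         intercept = intercept, provenance = provenance, fit = fit),
    class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model> %s (%s)\n", x$name, x$provenance))
  cat(sprintf("  intercept: %s\n",
              if (is.na(x$intercept)) "unknown" else format(x$intercept)))
  tab <- data.frame(term = names(x$beta), beta = unname(x$beta))
  if (!is.null(x$fit$se)) {
    tab$se <- unname(x$fit$se[tab$term])
    tab$ci_lower <- tab$beta - 1.96 * tab$se
    tab$ci_upper <- tab$beta + 1.96 * tab$se
  }
  print(tab, row.names = FALSE, digits = 4)
  if (!is.null(x$fit))
    cat(sprintf("  logLik %.2f  AIC %.2f  n = %d (%d events)\n",
                x$fit$loglik, x$fit$aic, x$fit$n, x$fit$n_events))
  invisible(x)
}

.term_from_list <- function(tl) {
  term_spec(name = tl$name, field = tl$field, encoding = tl$encoding,
            unit = tl$unit, cutpoint = tl$cutpoint,
            cutpoint_female = tl$cutpoint_female,
            direction = if (is.null(tl$direction)) "ge" else tl$direction,
            lower = tl$lower, upper = tl$upper, level = tl$level)
}

#' Read a risk model from a JSON model file
#'
#' @param path Path to a JSON model definition (name, provenance,
#'   intercept and a terms array each carrying field/encoding/beta and
#'   any cutpoints).
#' @return A [risk_model()].
#' @export
read_model <- function(path) {
  def <- jsonlite::read_json(path)
  terms <- lapply(def$terms, .term_from_list)
  beta <- vapply(def$terms, function(t) as.numeric(t$beta), 0)
  risk_model(name = def$name, terms = terms, beta = beta,
             intercept = if (is.null(def$intercept)) NA_real_
                         else as.numeric(def$intercept),
             provenance = def$provenance)
}

#' Load the bundled published models
#'
#' Returns the three published multivariate predictive functions for
#' incident type 2 diabetes with their published coefficients: the San
#' Antonio Heart Study (SAHS) model, the Atherosclerosis Risk in
#' Communities (ARIC) model and the Framingham Offspring (FRAM) model.
#' Glucose and lipid terms in SAHS/ARIC are on the mg/dl scale;
#' ethnicity is coded 1 for non-Chinese (Chinese reference) and SAHS
#' gender 1 for female (male reference).  FRAM is all-categorical; its
#' binary encodings (impaired fasting glucose 6.1-6.9 mmol/L, systolic
#' blood pressure >= 130 mmHg, triglyceride >= 1.7 mmol/L, low HDL
#' < 1.0 mmol/L in men / < 1.3 mmol/L in women, overweight 25 <= BMI
#' < 30, obese BMI >= 30) follow the conventions of the definitions the
#' models reference and are configurable in the model files.
#' Intercepts are unknown (`NA`) unless supplied in the model files.
#'
#' @param dir Directory with model JSON files; defaults to the bundled
#'   definitions.
#' @param asian_overweight If `TRUE`, the FRAM overweight band starts at
#'   BMI 23 (the WHO cutoff recommended for Asian populations) instead
#'   of 25.
#' @return Named list of [risk_model()] objects (`SAHS`, `ARIC`,
#'   `FRAM`).
#' @export
#' @examples
#' mods <- load_published_models()
#' mods$ARIC$beta[["fpg"]]
load_published_models <- function(dir = system.file("extdata", "models",
                                                    package = "riskrecal"),
                                  asian_overweight = FALSE) {
  paths <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
  models <- lapply(paths, read_model)
  names(models) <- vapply(models, `[[`, "", "name")
  if (asian_overweight && "FRAM" %in% names(models)) {
    i <- which(names(models$FRAM$beta) == "overweight")
    models$FRAM$terms[[i]]$lower <- 23
  }
  models[intersect(c("SAHS", "ARIC", "FRAM"), names(models))]
}

.encode_term <- function(term, cohort, factors) {
  v <- switch(term$encoding,
    linear = {
      x <- cohort[[term$field]]
      if (!is.null(term$unit) && identical(term$unit, "mg/dl") &&
          term$field %in% names(.field_analyte))
        x <- convert_units(x, .field_analyte[[term$field]],
                           "mmol/L", "mg/dl", factors)
      x
    },
    binary = as.numeric(cohort[[term$field]]),
    female = as.numeric(cohort$sex == "female"),
    non_chinese = as.numeric(cohort$ethnicity != "Chinese"),
    level = as.numeric(cohort[[term$field]] == term$level),
    threshold = {
      x <- cohort[[term$field]]
      cut <- rep(term$cutpoint, nrow(cohort))
      if (!is.null(term$cutpoint_female))
        cut[cohort$sex == "female"] <- term$cutpoint_female
      if (term$direction == "ge") as.numeric(x >= cut)
      else as.numeric(x < cut)
    },
    range = {
      x <- cohort[[term$field]]
      as.numeric(x >= term$lower & x < term$upper)
    },
    stop("unknown encoding: ", term$encoding))
  v
}

.term_fields <- function(term) {
  switch(term$encoding,
         female = "sex",
         non_chinese = "ethnicity",
         threshold = unique(c(term$field,
                              if (!is.null(term$cutpoint_female)) "sex")),
         term$field)
}

#' Encode subjects into a model's covariate space
#'
#' Evaluates every term of a model on every subject: unit conversions
#' for mg/dl terms, indicator evaluation at the model's cutpoints and
#' reference coding of factors.  The encoding is deterministic and
#' depends only on field values, never on row or column order.
#'
#' @param cohort A validated cohort data frame.
#' @param model A [risk_model()] (or a bare list of [term_spec()]s).
#' @param factors Unit conversion factors.
#' @return A numeric matrix, one row per subject, columns named and
#'   ordered as the model's terms.
#' @export
encode_subjects <- function(cohort, model,
                            factors = unit_conversion_factors()) {
  terms <- if (inherits(model, "risk_model")) model$terms else model
  validate_cohort(cohort)
  needed <- unique(unlist(lapply(terms, .term_fields)))
  absent <- setdiff(needed, names(cohort))
  if (length(absent) > 0)
    stop("cohort lacks field(s) required by the model: ",
         paste(absent, collapse = ", "))
  for (f in needed) {
    bad <- is.na(cohort[[f]])
    if (any(bad))
      stop(sprintf(
        "missing value in required field '%s' for subject(s): %s", f,
        paste(utils::head(cohort$id[bad], 5), collapse = ", ")))
  }
  X <- vapply(terms, .encode_term, numeric(nrow(cohort)),
              cohort = cohort, factors = factors)
  X <- matrix(X, nrow = nrow(cohort),
              dimnames = list(cohort$id,
                              vapply(terms, `[[`, "", "name")))
  X
}

#' Linear predictor of a risk model
#'
#' Computes `intercept + x %*% beta`.  When the model's intercept is
#' unknown the score cannot be anchored on the probability scale; pass
#' `rank_only = TRUE` to obtain the intercept-free score `x %*% beta`,
#' which preserves the risk ordering and is flagged as rank-only.
#'
#' @param model A [risk_model()].
#' @param x Encoded covariate matrix (or a single vector) aligned with
#'   the model's terms, as from [encode_subjects()].
#' @param rank_only Return the intercept-free score.
#' @return Numeric vector of linear predictors with attribute
#'   `rank_only`.
#' @export
linear_predictor <- function(model, x, rank_only = FALSE) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(model$beta))
    stop("covariate vector has ", ncol(x), " columns; model '",
         model$name, "' has ", length(model$beta), " terms")
  score <- drop(x %*% model$beta)
  if (rank_only) {
    attr(score, "rank_only") <- TRUE
    return(score)
  }
  if (is.na(model$intercept))
    stop("model '", model$name, "' has an unknown intercept; use ",
         "recalibrate() for absolute risks or rank_only = TRUE for ",
         "risk ordering")
  score <- score + model$intercept
  attr(score, "rank_only") <- FALSE
  score
}

#' Predict absolute diabetes risk
#'
#' Applies the logistic risk formula `p = 1 / (1 + exp(-y))` to the
#' model's linear predictor `y` for each subject.
#'
#' @inheritParams linear_predictor
#' @param cohort A validated cohort data frame.
#' @param factors Unit conversion factors.
#' @return A data frame of class `risk_prediction` with columns `id`,
#'   `model`, `linear_predictor`, `probability` (`NA` under
#'   `rank_only`), `recalibrated` (always `FALSE` here).
#' @export
predict_risk <- function(model, cohort, rank_only = FALSE,
                         factors = unit_conversion_factors()) {
  X <- encode_subjects(cohort, model, factors)
  y <- linear_predictor(model, X, rank_only = rank_only)
  out <- data.frame(
    id = cohort$id,
    model = model$name,
    linear_predictor = as.numeric(y),
    probability = if (rank_only) NA_real_ else stats::plogis(as.numeric(y)),
    recalibrated = FALSE,
    stringsAsFactors = FALSE)
  class(out) <- c("risk_prediction", class(out))
  out
}
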