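#' Default imputer variable set
#'
#' The inclusive baseline variable list used by the conditional models
#' when imputing missing follow-up glucose: demographics, blood
#' pressure, adiposity measures, lipids, baseline glucose, family
#' history, kidney function and insulin resistance.  Variables absent
#' from the supplied cohort are silently dropped.
#'
#' @return Character vector of field names.
#' @export
default_imputer_fields <- function() {
  c("age", "sex", "ethnicity", "sbp", "bmi", "hdl", "ldl", "fpg",
    "family_history_t2dm", "hip", "waist", "waist_hip_ratio",
    "creatinine", "triglyceride", "insulin_resistance", "fpg_followup")
}

# Draw from the Bayesian posterior predictive of a normal linear model:
# sigma^2 from the scaled inverse chi-squared, beta from its normal
# conditional, then observation noise.
.norm_draw_impute <- function(X_obs, y_obs, X_mis) {
  qrx <- qr(X_obs)
  keep <- qrx$pivot[seq_len(qrx$rank)]
  X_obs <- X_obs[, keep, drop = FALSE]
  X_mis <- X_mis[, keep, drop = FALSE]
  qrx <- qr(X_obs)
  beta_hat <- qr.coef(qrx, y_obs)
  res <- y_obs - X_obs %*% beta_hat
  df <- max(length(y_obs) - ncol(X_obs), 1)
  sigma2 <- sum(res^2) / stats::rchisq(1, df)
  R <- qr.R(qrx)
  beta <- beta_hat + sqrt(sigma2) *
    backsolve(R, stats::rnorm(ncol(X_obs)))
  drop(X_mis %*% beta) + stats::rnorm(nrow(X_mis), 0, sqrt(sigma2))
}

# Predictive-mean matching (type-1): parameters drawn as in the normal
# model, missing cells take the observed value of one of the k donors
# whose Bayesian-predicted mean is closest to the missing cell's.
.pmm_draw_impute <- function(X_obs, y_obs, X_mis, k = 5) {
  qrx <- qr(X_obs)
  keep <- qrx$pivot[seq_len(qrx$rank)]
  X_obs <- X_obs[, keep, drop = FALSE]
  X_mis <- X_mis[, keep, drop = FALSE]
  qrx <- qr(X_obs)
  beta_hat <- qr.coef(qrx, y_obs)
  res <- y_obs - X_obs %*% beta_hat
  df <- max(length(y_obs) - ncol(X_obs), 1)
  sigma2 <- sum(res^2) / stats::rchisq(1, df)
  R <- qr.R(qrx)
  beta <- beta_hat + sqrt(sigma2) *
    backsolve(R, stats::rnorm(ncol(X_obs)))
  mu_obs <- drop(X_obs %*% beta_hat)
  mu_mis <- drop(X_mis %*% beta)
  k <- min(k, length(y_obs))
  # nearest-mean donors found in a window around the insertion point of
  # the sorted predicted means
  ord <- order(mu_obs)
  mu_sorted <- mu_obs[ord]
  y_sorted <- y_obs[ord]
  n_obs <- length(mu_sorted)
  pos <- findInterval(mu_mis, mu_sorted)
  vapply(seq_along(mu_mis), function(i) {
    w <- max(1, pos[i] - k):min(n_obs, pos[i] + k)
    donors <- w[order(abs(mu_sorted[w] - mu_mis[i]))[seq_len(k)]]
    y_sorted[donors[sample.int(k, 1)]]
  }, 0)
}

.logit_draw_impute <- function(X_obs, y_obs, X_mis) {
  fit <- suppressWarnings(
    stats::glm.fit(X_obs, y_obs, family = stats::binomial()))
  co <- fit$coefficients
  co[is.na(co)] <- 0
  w <- fit$weights
  XtWX <- crossprod(X_obs * sqrt(w))
  V <- tryCatch(solve(XtWX), error = function(e) diag(1e-6, length(co)))
  beta <- co + drop(chol(V + diag(1e-10, length(co))) %*%
                      stats::rnorm(length(co)))
  p <- stats::plogis(drop(X_mis %*% beta))
  stats::rbinom(nrow(X_mis), 1, p)
}

.numeric_frame <- function(data, fields) {
  out <- data[fields]
  if ("sex" %in% fields) out$sex <- as.numeric(data$sex == "female")
  if ("ethnicity" %in% fields)
    out$ethnicity <- as.numeric(data$ethnicity != "Chinese")
  as.matrix(as.data.frame(lapply(out, as.numeric)))
}

#' Fully conditional specification multiple imputation
#'
#' Imputes missing values by chained conditional models: each
#' incomplete field is regressed on the other imputer fields.
#' Continuous fields are imputed by predictive-mean matching by default
#' (a Bayesian parameter draw followed by sampling the observed value
#' of one of the nearest-predicted-mean donors, which preserves
#' non-normal marginals such as the bimodal follow-up glucose), or by
#' the posterior predictive of a normal linear model
#' (`continuous_method = "norm"`); binary fields use a logistic model
#' with a parameter draw.  The conditionals are cycled a fixed number
#' of times per chain and `M` independent chains give `M` completed
#' datasets.  The run is fully reproducible from `seed`.
#'
#' @param cohort Cohort data frame.
#' @param fields Imputer field set (predictors and imputation targets);
#'   defaults to [default_imputer_fields()] intersected with the
#'   cohort's columns.  Fields that are complete serve as predictors
#'   only.
#' @param M Number of imputations.
#' @param cycles Conditional-model cycles per chain.
#' @param seed Integer seed.
#' @param continuous_method `"pmm"` (predictive-mean matching, default)
#'   or `"norm"` (normal posterior predictive) for continuous fields.
#' @param donors Number of candidate donors for predictive-mean
#'   matching.
#' @return An object of class `imputation_result`: `M`, `datasets`
#'   (list of completed cohorts), `imputed_fields`, `seed`.
#' @export
fcs_impute <- function(cohort, fields = NULL, M = 20, cycles = 10,
                       seed = 1, continuous_method = c("pmm", "norm"),
                       donors = 5) {
  continuous_method <- match.arg(continuous_method)
  validate_cohort(cohort)
  if (is.null(fields))
    fields <- intersect(default_imputer_fields(), names(cohort))
  absent <- setdiff(fields, names(cohort))
  if (length(absent) > 0)
    stop("imputer field(s) not in cohort: ", paste(absent, collapse = ", "))
  miss <- vapply(fields, function(f) sum(is.na(cohort[[f]])), 0L)
  targets <- names(miss)[miss > 0]
  targets <- targets[order(miss[targets])]
  if (length(targets) > 0 && any(miss[targets] == nrow(cohort))) {
    warning("field(s) with no observed values skipped: ",
            paste(targets[miss[targets] == nrow(cohort)], collapse = ", "))
    targets <- targets[miss[targets] < nrow(cohort)]
  }
  binary <- vapply(targets, function(f)
    all(cohort[[f]] %in% c(0, 1, NA)), TRUE)
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1, M)
  datasets <- lapply(seq_len(M), function(m) {
    set.seed(sub_seeds[m])
    dat <- cohort
    for (f in targets) {
      na <- is.na(dat[[f]])
      dat[[f]][na] <- sample(dat[[f]][!na], sum(na), replace = TRUE)
    }
    if (length(targets) > 0) {
      for (cyc in seq_len(cycles)) {
        for (f in targets) {
          preds <- setdiff(fields, f)
          Z <- cbind(`(Intercept)` = 1, .numeric_frame(dat, preds))
          obs <- !is.na(cohort[[f]])
          if (binary[[f]]) {
            dat[[f]][!obs] <- .logit_draw_impute(
              Z[obs, , drop = FALSE], dat[[f]][obs],
              Z[!obs, , drop = FALSE])
          } else if (continuous_method == "pmm") {
            dat[[f]][!obs] <- .pmm_draw_impute(
              Z[obs, , drop = FALSE], dat[[f]][obs],
              Z[!obs, , drop = FALSE], k = donors)
          } else {
            v <- .norm_draw_impute(
              Z[obs, , drop = FALSE], dat[[f]][obs],
              Z[!obs, , drop = FALSE])
            if (f %in% .continuous_fields)
              v <- pmax(v, .Machine$double.eps)
            dat[[f]][!obs] <- v
          }
        }
      }
    }
    dat
  })
  structure(list(M = M, datasets = datasets, imputed_fields = targets,
                 seed = seed),
            class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  cat(sprintf("<imputation_result> M = %d chains; imputed field(s): %s\n",
              x$M,
              if (length(x$imputed_fields)) paste(x$imputed_fields,
                                                  collapse = ", ")
              else "none"))
  invisible(x)
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Combines per-imputation point estimates and variances: the pooled
#' estimate is the mean `Qbar`, the within-imputation variance `W` the
#' mean of the variances, the between-imputation variance `B` the
#' sample variance of the estimates, and the total variance
#' `T = W + (1 + 1/M) B`.
#'
#' @param estimates M x k matrix (or list of vectors) of per-imputation
#'   estimates.
#' @param variances M x k matrix (or list) of per-imputation squared
#'   standard errors.
#' @return Data frame with one row per coefficient: `estimate`,
#'   `within`, `between`, `total`, `se`, `df` (Rubin's large-sample
#'   degrees of freedom), `ci_lower`, `ci_upper`.
#' @export
#' @examples
#' rubin_pool(rbind(1, 3), rbind(1, 1))
rubin_pool <- function(estimates, variances) {
  if (is.list(estimates) && !is.data.frame(estimates))
    estimates <- do.call(rbind, estimates)
  if (is.list(variances) && !is.data.frame(variances))
    variances <- do.call(rbind, variances)
  estimates <- as.matrix(estimates)
  variances <- as.matrix(variances)
  if (!all(dim(estimates) == dim(variances)))
    stop("estimates and variances must have identical dimensions")
  M <- nrow(estimates)
  if (M < 2) stop("pooling requires M >= 2 imputations")
  qbar <- colMeans(estimates)
  w <- colMeans(variances)
  b <- apply(estimates, 2, stats::var)
  tot <- w + (1 + 1 / M) * b
  r <- ifelse(b > 0, (1 + 1 / M) * b / w, 0)
  df <- ifelse(b > 0, (M - 1) * (1 + 1 / r)^2, Inf)
  se <- sqrt(tot)
  tcrit <- stats::qt(0.975, pmin(df, 1e9))
  out <- data.frame(
    term = if (!is.null(colnames(estimates))) colnames(estimates)
           else paste0("q", seq_along(qbar)),
    estimate = qbar, within = w, between = b, total = tot, se = se,
    df = df, ci_lower = qbar - tcrit * se, ci_upper = qbar + tcrit * se,
    row.names = NULL)
  out
}

#' Fit a local model on each imputed dataset and pool
#'
#' Re-derives the outcome from each completed dataset's follow-up
#' glucose and diagnosis flag, fits the local logistic model on each,
#' and pools intercept and coefficients by Rubin's rules.
#'
#' @param imputations An `imputation_result` from [fcs_impute()].
#' @param terms Term list or [risk_model()] to fit.
#' @param name Model name for the per-imputation fits.
#' @param factors Unit conversion factors.
#' @return List with `pooled` (Rubin-pooled coefficient table including
#'   the intercept) and `fits` (the per-imputation [risk_model()]s).
#' @export
pool_local_fit <- function(imputations, terms, name = "local-MI",
                           factors = unit_conversion_factors()) {
  stopifnot(inherits(imputations, "imputation_result"))
  fits <- lapply(imputations$datasets, function(dat) {
    if ("fpg_followup" %in% names(dat)) {
      dx <- if ("physician_dx_followup" %in% names(dat))
        dat$physician_dx_followup else 0
      dat$outcome_t2dm <- define_outcome(dat$fpg_followup, dx)
    }
    fit_local_model(dat, terms, name = name, factors = factors)
  })
  est <- t(vapply(fits, function(f) c(`(Intercept)` = f$intercept, f$beta),
                  numeric(length(fits[[1]]$beta) + 1)))
  vars <- t(vapply(fits, function(f)
    c(f$fit$se_intercept, unname(f$fit$se))^2,
    numeric(length(fits[[1]]$beta) + 1)))
  colnames(vars) <- colnames(est)
  list(pooled = rubin_pool(est, vars), fits = fits)
}
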