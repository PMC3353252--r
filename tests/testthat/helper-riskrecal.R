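# Hand-built subjects for encoding/eligibility tests.
make_subjects <- function(n = 1, ...) {
  base <- data.frame(
    id = sprintf("T%03d", seq_len(n)),
    age = 40, sex = "male", ethnicity = "Chinese",
    fpg = 5.0, two_hpg = 6.0, sbp = 120, hdl = 1.2,
    triglyceride = 1.2, bmi = 23, waist = 80, height = 170,
    family_history_t2dm = 0, diagnosed_t2dm = 0,
    fpg_followup = 5.5, physician_dx_followup = 0,
    outcome_t2dm = 0, stringsAsFactors = FALSE)
  mods <- list(...)
  for (nm in names(mods)) base[[nm]] <- mods[[nm]]
  base
}

# All-pairs Mann-Whitney AUC, ties counted one half.
brute_auc <- function(scores, outcomes) {
  cases <- scores[outcomes == 1]
  controls <- scores[outcomes == 0]
  tot <- 0
  for (a in cases) for (b in controls)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cases) * length(controls))
}

# Explicit reclassification-table NRI.
brute_nri <- function(p_new, p_old, outcomes,
                      cuts = c(0.10, 0.20, 0.30, 0.40, 0.50)) {
  categ <- function(p) {
    k <- 1
    for (c0 in cuts) if (p > c0) k <- k + 1
    k
  }
  eu <- ed <- nu <- nd <- 0
  for (i in seq_along(p_new)) {
    cn <- categ(p_new[i])
    co <- categ(p_old[i])
    if (outcomes[i] == 1) {
      if (cn > co) eu <- eu + 1
      if (cn < co) ed <- ed + 1
    } else {
      if (cn > co) nu <- nu + 1
      if (cn < co) nd <- nd + 1
    }
  }
  n1 <- sum(outcomes)
  n0 <- sum(1 - outcomes)
  list(events = (eu - ed) / n1, nonevents = (nd - nu) / n0,
       total = (eu - ed) / n1 + (nd - nu) / n0)
}

# Small generated cohort reused across tests.
small_cohort <- function(n = 800, seed = 42, ...) {
  generate_cohort(cohort_config(n = n, ...), seed = seed)
}
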