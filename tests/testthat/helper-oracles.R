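# Independent oracles and fixtures shared across tests.

# Truncated-series matrix exponential: sum_{j<=k} (tQ)^j / j!.
# Deliberately naive and independent of the implementation path.
expm_series <- function(Q, t, k = 60) {
  n <- nrow(Q)
  term <- diag(n)
  acc <- diag(n)
  M <- t * Q
  for (j in seq_len(k)) {
    term <- term %*% M / j
    acc <- acc + term
  }
  dimnames(acc) <- dimnames(Q)
  acc
}

# Random valid intensity matrix on the default 8-arrow structure, with
# rates in a realistic per-year range.
random_valid_Q <- function(struct = transition_structure(),
                           rate_range = c(0.02, 0.6)) {
  n <- length(struct$states)
  Q <- matrix(0, n, n, dimnames = list(struct$states, struct$states))
  rates <- stats::runif(nrow(struct$arrows), rate_range[1], rate_range[2])
  Q[cbind(struct$arrows$from, struct$arrows$to)] <- rates
  diag(Q) <- -rowSums(Q)
  Q
}

# Two-state one-way chain ("1" -> "2" at rate lambda) as an
# intensity_model, for closed-form likelihood checks.
two_state_model <- function(lambda) {
  st <- transition_structure(states = c("A", "B"),
                             arrows = data.frame(from = "A", to = "B"))
  intensity_model(st, log(lambda))
}

# Hand-constructed raw questionnaire records exercising the coding rules:
#  - r1: age 12 entrant, never -> e-cig -> non-current
#  - r2: first seen at 17 as a non-user (assumed non-current), then smokes
#  - r3: young never user throughout
#  - r4: has one record with a missing smoking response (record dropped)
#  - r5: missing ethnicity (subject dropped)
#  - r6: single wave only (subject dropped)
raw_fixture <- function() {
  rec <- function(id, wave, t, age, ecig, smoke, sex = "female",
                  eth = "white", inc = 1500, ad = 2, ch = 1, w = 1) {
    data.frame(subject_id = id, wave = wave, interview_time = t,
               age_years = age, ecig_response = ecig,
               smoke_response = smoke, sex = sex, ethnicity = eth,
               household_income_monthly = inc, household_adults = ad,
               household_children_under14 = ch, survey_weight = w,
               stringsAsFactors = FALSE)
  }
  rbind(
    rec("r1", 8, 0, 12, "never", "no"),
    rec("r1", 9, 1, 13, "less than monthly", "no"),
    rec("r1", 10, 2, 14, "past not now", "no"),
    rec("r2", 8, 0, 17, "never", "no"),
    rec("r2", 9, 1, 18, "never", "yes"),
    rec("r3", 8, 0, 11, "never", "no"),
    rec("r3", 9, 1, 12, "never", "no"),
    rec("r4", 8, 0, 15, "never", "no"),
    rec("r4", 9, 1, 16, "never", NA),
    rec("r4", 10, 2, 17, "tried once or twice", "no"),
    rec("r5", 8, 0, 14, "never", "no", eth = NA),
    rec("r5", 9, 1, 15, "never", "no", eth = NA),
    rec("r6", 8, 0, 20, "at least weekly", "no")
  )
}

# Small deterministic two-subject panel used for hand-computed
# likelihood and crude-rate tallies (4 observation intervals).
tiny_panel <- function() {
  data.frame(
    subject_id = c("a", "a", "a", "b", "b", "b"),
    time = c(0, 1, 2.5, 0, 2, 3),
    state = c("NEVER", "ECIG_ONLY", "SMOKING",
              "NEVER", "NEVER", "ECIG_ONLY"),
    weight = c(2, 2, 2, 1, 1, 1),
    stringsAsFactors = FALSE
  )
}

# Moderate shared synthetic fit, computed once per test run.
shared_fit_env <- new.env(parent = emptyenv())
shared_sim_fit <- function() {
  if (is.null(shared_fit_env$fit)) {
    cfg <- sim_config(n_subjects = 4000, seed = 404)
    sim <- simulate_panel(cfg)
    shared_fit_env$sim <- sim
    shared_fit_env$fit <- fit_msm(sim$panel)
  }
  list(sim = shared_fit_env$sim, fit = shared_fit_env$fit)
}
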