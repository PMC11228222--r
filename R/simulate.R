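#' Default ground-truth intensity matrix
#'
#' A realistic generator for synthetic panels, reverse-engineered from the
#' published one-year transition matrix for UK youth: the matrix logarithm
#' of the row-normalised published matrix, projected onto the permitted
#' arrow set (off-arrow entries zeroed, any tiny negative off-diagonals
#' clamped to zero, diagonal reset). This is an approximation for
#' simulation purposes, not a published intensity estimate; its one-year
#' matrix exponential reproduces the published matrix to about 4e-4.
#'
#' @param struct A `transition_structure`.
#' @return Valid intensity matrix with state dimnames.
#' @export
#' @examples
#' round(default_truth_Q(), 3)
default_truth_Q <- function(struct = transition_structure()) {
  P <- normalise_printed(reference_one_year_matrix())
  L <- pracma::logm(P)
  A <- arrow_matrix(struct)
  Q <- L
  Q[!A & row(Q) != col(Q)] <- 0
  Q[Q < 0 & row(Q) != col(Q)] <- 0
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  dimnames(Q) <- list(struct$states, struct$states)
  validate_intensity_matrix(Q, struct)
  Q
}

#' Default covariate-free ground-truth model
#' @param struct A `transition_structure`.
#' @return An `intensity_model` with [default_truth_Q()] baselines.
#' @export
default_truth_model <- function(struct = transition_structure()) {
  Q <- default_truth_Q(struct)
  intensity_model(struct,
                  log(Q[cbind(struct$arrows$from, struct$arrows$to)]))
}

#' Baseline state distribution by age band
#'
#' Default conditional distribution of the baseline nicotine-product-use
#' state given entry age band, shaped like the baseline composition of a
#' large UK youth household panel: never use dominates at 10-13 and falls
#' steeply with age while non-current use and smoking rise.
#'
#' @return 4x4 matrix, rows age bands, columns states, rows summing to 1.
#' @export
default_init_state_by_age <- function() {
  M <- rbind(
    "10-13" = c(3540, 40, 30, 38),
    "14-17" = c(1941, 396, 115, 194),
    "18-21" = c(1185, 663, 89, 351),
    "22-25" = c(607, 609, 103, 328)
  )
  colnames(M) <- nicotine_states()
  M / rowSums(M)
}

#' Simulation configuration for synthetic panels
#'
#' Bundles the design of the emulated survey: cohort size, annual waves
#' with interview-date jitter, entry-age and covariate marginals shaped
#' like a UK youth household panel (47% male, 71% white, 39/34/28% income
#' tertiles), per-wave attrition, positive mean-1 survey weights, the
#' ground-truth intensity model, and whether to render sampled states back
#' into wave-appropriate questionnaire responses (binary at wave 7,
#' six-category at waves 8+).
#'
#' @param n_subjects Number of subjects.
#' @param n_waves Number of annual waves (nominal spacing `wave_spacing`).
#' @param first_wave Index of the first wave (wave 7 uses the binary
#'   e-cigarette question when responses are emulated).
#' @param wave_spacing Nominal years between waves.
#' @param jitter_sd SD (years) of interview-date jitter around the nominal
#'   schedule.
#' @param age_band_probs Entry age-band marginal.
#' @param init_state_by_age Baseline-state distribution conditional on
#'   entry age band.
#' @param p_male,p_white Sex and ethnicity marginals.
#' @param income_probs Income tertile marginal (normalised internally).
#' @param attrition Per-wave probability of dropping out after each
#'   retained wave (missing completely at random). Subjects also age out
#'   of the 10-25 study range.
#' @param weight_sdlog SD of log survey weights (lognormal, mean 1).
#' @param emulate_responses Also render raw questionnaire records.
#' @param truth Ground-truth `intensity_model`.
#' @param study_start Calendar date of time 0 (for interview dates).
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_subjects = 10000, n_waves = 6, first_wave = 7,
                       wave_spacing = 1, jitter_sd = 0.08,
                       age_band_probs = c("10-13" = 0.36, "14-17" = 0.26,
                                          "18-21" = 0.22, "22-25" = 0.16),
                       init_state_by_age = default_init_state_by_age(),
                       p_male = 0.47, p_white = 0.71,
                       income_probs = c(low = 0.39, mid = 0.34,
                                        high = 0.28),
                       attrition = 0.15, weight_sdlog = 0.3,
                       emulate_responses = FALSE,
                       truth = default_truth_model(),
                       study_start = as.Date("2015-07-01"),
                       seed = 1) {
  income_probs <- income_probs / sum(income_probs)
  age_band_probs <- age_band_probs / sum(age_band_probs)
  stopifnot(all(income_probs >= 0), all(age_band_probs >= 0),
            p_male >= 0, p_male <= 1, p_white >= 0, p_white <= 1,
            attrition >= 0, attrition < 1, n_waves >= 2,
            inherits(truth, "intensity_model"))
  stopifnot(all(abs(rowSums(init_state_by_age) - 1) < 1e-8))
  validate_intensity_matrix(build_Q(truth), truth$struct)
  structure(
    list(n_subjects = n_subjects, n_waves = n_waves,
         first_wave = first_wave, wave_spacing = wave_spacing,
         jitter_sd = jitter_sd, age_band_probs = age_band_probs,
         init_state_by_age = init_state_by_age, p_male = p_male,
         p_white = p_white, income_probs = income_probs,
         attrition = attrition, weight_sdlog = weight_sdlog,
         emulate_responses = emulate_responses, truth = truth,
         study_start = study_start, seed = seed),
    class = "sim_config"
  )
}

#' Exact event-time simulation of one continuous-time trajectory
#'
#' Simulates the continuous-time state path of the assumed model by
#' drawing exponential sojourn times (rate equal to the total exit
#' intensity of the current state) and destinations proportional to the
#' off-diagonal intensities, restarting at covariate change points
#' (memorylessness makes the restart exact).
#'
#' @param model An `intensity_model`.
#' @param initial_state State label at `t_start`.
#' @param t_start,t_end Time window in years.
#' @param z_path Optional data.frame of covariate change points: column
#'   `time` (segment start) plus one column per model term; `NULL` means
#'   baseline throughout.
#' @return data.frame `time`, `state` of the initial state and each jump.
#' @export
simulate_trajectory <- function(model, initial_state, t_start, t_end,
                                z_path = NULL) {
  stopifnot(inherits(model, "intensity_model"), t_end > t_start)
  states <- model$struct$states
  stopifnot(initial_state %in% states)
  if (is.null(z_path)) {
    seg_t <- t_start
    Qs <- list(build_Q(model))
  } else {
    z_path <- z_path[order(z_path$time), , drop = FALSE]
    keep <- z_path$time < t_end
    z_path <- z_path[keep, , drop = FALSE]
    seg_t <- pmax(z_path$time, t_start)
    if (!length(seg_t) || seg_t[1] > t_start) {
      stop("z_path must cover t_start")
    }
    Qs <- lapply(seq_len(nrow(z_path)), function(i) {
      z <- unlist(z_path[i, model$terms, drop = FALSE])
      build_Q(model, z)
    })
  }
  seg_end <- c(seg_t[-1], t_end)
  t <- t_start
  s <- match(initial_state, states)
  out_t <- t_start
  out_s <- initial_state
  for (k in seq_along(seg_t)) {
    Q <- Qs[[k]]
    while (t < seg_end[k]) {
      rate <- -Q[s, s]
      if (rate <= 0) {
        t <- seg_end[k]
        break
      }
      soj <- stats::rexp(1, rate)
      if (t + soj >= seg_end[k]) {
        t <- seg_end[k]
        break
      }
      t <- t + soj
      p <- Q[s, ]
      p[s] <- 0
      s <- sample.int(length(states), 1, prob = p)
      out_t <- c(out_t, t)
      out_s <- c(out_s, states[s])
    }
  }
  data.frame(time = out_t, state = out_s, stringsAsFactors = FALSE)
}

# probabilities P(dt)[from, ] for many (dt, from) pairs under one Q;
# rows renormalised to guard eigen round-off
.tpm_rows <- function(Q, dt, from) {
  n <- nrow(Q)
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  ok <- FALSE
  if (!is.null(eg)) {
    Vinv <- tryCatch(solve(eg$vectors), error = function(e) NULL)
    if (!is.null(Vinv)) {
      recon <- Re(eg$vectors %*% diag(eg$values, n) %*% Vinv)
      ok <- max(abs(recon - Q)) < 1e-9 * max(1, max(abs(Q)))
    }
  }
  if (ok) {
    A <- exp(outer(dt, eg$values))
    V <- eg$vectors
    P <- sapply(seq_len(n), function(s)
      Re(rowSums(V[from, , drop = FALSE] * A *
                   matrix(Vinv[, s], length(dt), n, byrow = TRUE))))
    P <- matrix(P, ncol = n)
  } else {
    P <- matrix(NA_real_, length(dt), n)
    for (u in unique(dt)) {
      M <- as.matrix(Matrix::expm(u * Q))
      idx <- which(dt == u)
      P[idx, ] <- M[from[idx], , drop = FALSE]
    }
  }
  P[!is.finite(P) | P < 0] <- 0
  P / rowSums(P)
}

# sample next states given current states, one Q, per-row dt
.sample_next_state <- function(Q, dt, from) {
  P <- .tpm_rows(Q, dt, from)
  cum <- t(apply(P, 1, cumsum))
  u <- stats::runif(length(from))
  1L + rowSums(u > cum + 1e-15)
}

#' Simulate a synthetic survey panel
#'
#' End-to-end generator: draws covariates, entry ages, survey weights and
#' baseline states; samples the state at each retained interview exactly
#' (the skeleton of a continuous-time Markov chain observed at interview
#' times is a Markov chain with transition matrices `P(dt) = exp(dt Q)`);
#' applies attrition and ageing out of the 10-25 range; and optionally
#' renders states back into wave-appropriate questionnaire responses.
#' Models whose terms include age-band effects are simulated through the
#' event-level path sampler with change points at band-crossing birthdays.
#'
#' @param config A [sim_config()].
#' @return List with `panel` (coded-panel schema: subject_id, time, wave,
#'   state, age_years, age_band, sex, ethnicity, income_tertile, weight,
#'   assumed_noncurrent, interview_date), `raw` (raw-record data.frame
#'   when `emulate_responses`, else `NULL`), `truth`, and `config`.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  W <- config$n_waves
  bands <- names(config$age_band_probs)
  band_lo <- c("10-13" = 10, "14-17" = 14, "18-21" = 18, "22-25" = 22)
  band_hi <- c("10-13" = 13, "14-17" = 17, "18-21" = 21, "22-25" = 25)

  entry_band <- sample(bands, n, replace = TRUE,
                       prob = config$age_band_probs)
  age_entry <- band_lo[entry_band] +
    floor(stats::runif(n) * (band_hi[entry_band] - band_lo[entry_band] + 1))
  sex <- sample(c("male", "female"), n, replace = TRUE,
                prob = c(config$p_male, 1 - config$p_male))
  ethnicity <- sample(c("white", "ethnic minority"), n, replace = TRUE,
                      prob = c(config$p_white, 1 - config$p_white))
  income <- sample(names(config$income_probs), n, replace = TRUE,
                   prob = config$income_probs)
  weight <- stats::rlnorm(n, -config$weight_sdlog^2 / 2,
                          config$weight_sdlog)

  # interview schedule with jitter; nominal annual spacing dominates the
  # jitter so times stay increasing (sorted defensively anyway)
  times <- outer(rep(1, n), (seq_len(W) - 1) * config$wave_spacing) +
    matrix(stats::rnorm(n * W, 0, config$jitter_sd), n, W)
  times <- t(apply(times, 1, sort))

  # retained waves: MCAR attrition after each wave, plus ageing out at 25
  drop_u <- matrix(stats::runif(n * (W - 1)), n, W - 1)
  stays <- drop_u > config$attrition
  k_attr <- 1L + apply(stays, 1, function(r) {
    f <- which(!r)
    if (length(f)) f[1] - 1L else length(r)
  })
  k_age <- pmin(W, 26L - age_entry)
  K <- pmin(k_attr, k_age)

  # baseline state given entry age band
  init_p <- config$init_state_by_age[entry_band, , drop = FALSE]
  u <- stats::runif(n)
  cum <- t(apply(init_p, 1, cumsum))
  s0 <- 1L + rowSums(u > cum + 1e-15)

  states_idx <- matrix(NA_integer_, n, W)
  states_idx[, 1] <- s0
  truth <- config$truth
  state_labels <- truth$struct$states

  age_terms <- any(grepl("age_band", truth$terms))
  if (!age_terms) {
    # fixed covariates: group subjects by dummy pattern, vectorised waves
    if (length(truth$terms)) {
      fac <- data.frame(
        age_band = factor(entry_band,
                          levels = c("14-17", "10-13", "18-21", "22-25")),
        sex = factor(sex, levels = c("female", "male")),
        ethnicity = factor(ethnicity,
                           levels = c("white", "ethnic minority")),
        income_tertile = factor(income, levels = c("low", "mid", "high"))
      )
      mm <- stats::model.matrix(~ ., data = fac)[, -1, drop = FALSE]
      missing_terms <- setdiff(truth$terms, colnames(mm))
      if (length(missing_terms)) {
        stop("truth model terms not generated by the covariate design: ",
             paste(missing_terms, collapse = ", "))
      }
      Zt <- mm[, truth$terms, drop = FALSE]
      pat <- apply(Zt, 1, paste, collapse = "\r")
    } else {
      Zt <- matrix(0, n, 0)
      pat <- rep("", n)
    }
    upat <- unique(pat)
    for (g in seq_along(upat)) {
      gi <- which(pat == upat[g])
      z <- if (length(truth$terms)) Zt[gi[1], ] else NULL
      Q <- build_Q(truth, z)
      for (j in seq_len(W - 1)) {
        act <- gi[K[gi] > j]
        if (!length(act)) next
        dt <- times[act, j + 1] - times[act, j]
        states_idx[act, j + 1] <-
          .sample_next_state(Q, dt, states_idx[act, j])
      }
    }
  } else {
    # age-band effects: event-level path with birthday change points
    for (i in seq_len(n)) {
      if (K[i] < 2) next
      zp <- .age_z_path(truth, age_entry[i], sex[i], ethnicity[i],
                        income[i], times[i, 1], times[i, K[i]])
      tr <- simulate_trajectory(truth, state_labels[states_idx[i, 1]],
                                times[i, 1], times[i, K[i]], zp)
      for (j in 2:K[i]) {
        states_idx[i, j] <-
          match(tr$state[max(which(tr$time <= times[i, j]))],
                state_labels)
      }
    }
  }

  # assemble long panel of retained waves (vectorised)
  keep_subj <- which(K >= 2)
  si <- rep(keep_subj, K[keep_subj])
  jw <- sequence(K[keep_subj])
  panel <- data.frame(
    subject_id = sprintf("S%06d", si),
    time = times[cbind(si, jw)],
    wave = config$first_wave + jw - 1L,
    state = state_labels[states_idx[cbind(si, jw)]],
    age_years = age_entry[si] + jw - 1L,
    sex = sex[si], ethnicity = ethnicity[si],
    income_tertile = income[si],
    weight = weight[si],
    stringsAsFactors = FALSE
  )
  panel$age_band <- cut(panel$age_years, breaks = c(9, 13, 17, 21, 25),
                        labels = c("10-13", "14-17", "18-21", "22-25"))
  panel$age_band <- factor(panel$age_band,
                           levels = c("14-17", "10-13", "18-21", "22-25"))
  panel$sex <- factor(panel$sex, levels = c("female", "male"))
  panel$ethnicity <- factor(panel$ethnicity,
                            levels = c("white", "ethnic minority"))
  panel$income_tertile <- factor(panel$income_tertile,
                                 levels = c("low", "mid", "high"))
  panel$assumed_noncurrent <- FALSE
  panel$interview_date <- config$study_start +
    round(panel$time * 365.25)
  panel <- panel[, c("subject_id", "time", "wave", "state", "age_years",
                     "age_band", "sex", "ethnicity", "income_tertile",
                     "weight", "assumed_noncurrent", "interview_date")]
  rownames(panel) <- NULL

  raw <- NULL
  if (config$emulate_responses) {
    raw <- emulate_responses(panel, config)
  }
  list(panel = panel, raw = raw, truth = truth, config = config)
}

# covariate change-point path over [t0, t1] for age-band-effect models
.age_z_path <- function(model, age_entry, sex, ethnicity, income, t0, t1) {
  crossings <- c(14, 18, 22) - age_entry + t0
  cuts <- sort(unique(c(t0, crossings[crossings > t0 & crossings < t1])))
  fac <- data.frame(
    age_band = factor(
      cut(age_entry + (cuts - t0), breaks = c(9, 13, 17, 21, 25),
          labels = c("10-13", "14-17", "18-21", "22-25")),
      levels = c("14-17", "10-13", "18-21", "22-25")),
    sex = factor(sex, levels = c("female", "male")),
    ethnicity = factor(ethnicity, levels = c("white", "ethnic minority")),
    income_tertile = factor(income, levels = c("low", "mid", "high"))
  )
  mm <- stats::model.matrix(~ ., data = fac)[, -1, drop = FALSE]
  zp <- as.data.frame(mm[, model$terms, drop = FALSE])
  zp$time <- cuts
  zp
}

#' Render panel states back into questionnaire responses
#'
#' Produces a raw-record data.frame in the questionnaire schema from a
#' simulated panel: never users answer "never"/"no"; non-current users
#' answer "past not now" at six-category waves (the binary wave-7 question
#' cannot express prior use, so they answer "no" there); e-cigarette
#' users answer a current-use category; smokers answer "yes" to the
#' smoking question, with a fraction also reporting current e-cigarette
#' use (dual use). Household income, adults and children counts are drawn
#' consistent with the subject's income tertile under the modified OECD
#' scale, so the coding flow reproduces the tertile exactly.
#'
#' @param panel Simulated panel from [simulate_panel()].
#' @param config The `sim_config` used (for the wave-7 flag and cutoffs).
#' @param p_dual Probability a smoker also reports current e-cigarette
#'   use.
#' @return data.frame in the raw-record schema.
#' @export
emulate_responses <- function(panel, config, p_dual = 0.3) {
  n <- nrow(panel)
  binary <- panel$wave == 7
  current_cats <- c("tried once or twice", "less than monthly",
                    "monthly not weekly", "at least weekly")
  ecig <- character(n)
  smoke <- rep("no", n)

  nv <- panel$state == "NEVER"
  ecig[nv] <- ifelse(binary[nv], "no", "never")
  nc <- panel$state == "NONCURRENT"
  ecig[nc] <- ifelse(binary[nc], "no", "past not now")
  ec <- panel$state == "ECIG_ONLY"
  ecig[ec] <- ifelse(binary[ec], "yes",
                     sample(current_cats, sum(ec), replace = TRUE))
  sm <- panel$state == "SMOKING"
  smoke[sm] <- "yes"
  dual <- sm & stats::runif(n) < p_dual
  ecig[sm & !dual] <- ifelse(binary[sm & !dual], "no", "never")
  ecig[dual] <- ifelse(binary[dual], "yes",
                       sample(current_cats, sum(dual), replace = TRUE))

  # household income consistent with the subject's tertile
  cuts <- income_tertile_cutoffs()
  first <- !duplicated(panel$subject_id)
  tert <- as.character(panel$income_tertile)[first]
  ns <- sum(first)
  eq_inc <- numeric(ns)
  eq_inc[tert == "low"] <- stats::runif(sum(tert == "low"), 500,
                                        cuts[1] - 1)
  eq_inc[tert == "mid"] <- stats::runif(sum(tert == "mid"), cuts[1],
                                        cuts[2])
  eq_inc[tert == "high"] <- stats::runif(sum(tert == "high"),
                                         cuts[2] + 1, 3500)
  adults <- sample(1:3, ns, replace = TRUE, prob = c(0.3, 0.5, 0.2))
  children <- sample(0:3, ns, replace = TRUE,
                     prob = c(0.5, 0.25, 0.15, 0.1))
  fct <- 1 + 0.5 * (adults - 1) + 0.3 * children
  sid <- panel$subject_id[first]
  idx <- match(panel$subject_id, sid)

  data.frame(
    subject_id = panel$subject_id,
    wave = panel$wave,
    interview_time = panel$time,
    interview_date = panel$interview_date,
    age_years = panel$age_years,
    ecig_response = ecig,
    smoke_response = smoke,
    sex = as.character(panel$sex),
    ethnicity = as.character(panel$ethnicity),
    household_income_monthly = (eq_inc * fct)[idx],
    household_adults = adults[idx],
    household_children_under14 = children[idx],
    survey_weight = panel$weight,
    stringsAsFactors = FALSE
  )
}

#' Observe continuous-time trajectories at interview times
#'
#' Samples the state of each trajectory at its interview times, applies
#' missing-completely-at-random attrition, and drops subjects with fewer
#' than two retained interviews.
#'
#' @param trajectories List of data.frames from [simulate_trajectory()].
#' @param wave_times List (or matrix rows) of interview times per subject.
#' @param attrition Per-wave dropout probability after each retained wave.
#' @param weights Subject weights (recycled).
#' @param seed Integer seed for the attrition draws.
#' @return Panel data.frame `subject_id`, `time`, `wave`, `state`,
#'   `weight`.
#' @export
observe_panel <- function(trajectories, wave_times, attrition = 0,
                          weights = 1, seed = 1) {
  set.seed(seed)
  n <- length(trajectories)
  if (is.matrix(wave_times)) {
    wave_times <- split(wave_times, row(wave_times))
  }
  stopifnot(length(wave_times) == n)
  weights <- rep_len(weights, n)
  rows <- lapply(seq_len(n), function(i) {
    tt <- sort(wave_times[[i]])
    keep <- 1L
    for (j in seq_along(tt)[-1]) {
      if (stats::runif(1) < attrition) break
      keep <- j
    }
    tt <- tt[seq_len(keep)]
    tr <- trajectories[[i]]
    st <- vapply(tt, function(t0)
      tr$state[max(which(tr$time <= t0 + 1e-12))], character(1))
    data.frame(subject_id = sprintf("S%06d", i), time = tt,
               wave = seq_along(tt), state = st, weight = weights[i],
               stringsAsFactors = FALSE)
  })
  drop_singletons(do.call(rbind, rows))
}

#' Replicated recovery suite for simulation studies
#'
#' A seeded bundle of replicate synthetic panels sharing one ground truth,
#' for bias and coverage computations. Replicates are realised lazily so
#' large suites do not need to be held in memory at once.
#'
#' @param config A [sim_config()] (its `seed` seeds the whole suite).
#' @param n_replicates Number of replicates.
#' @return Object of class `recovery_suite` with `seeds`, `config`.
#' @export
make_recovery_suite <- function(config, n_replicates = 50) {
  stopifnot(inherits(config, "sim_config"), n_replicates >= 1)
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1, n_replicates)
  structure(list(config = config, seeds = seeds,
                 n_replicates = n_replicates),
            class = "recovery_suite")
}

#' Realise one replicate of a recovery suite
#' @param suite A `recovery_suite`.
#' @param i Replicate index.
#' @return The [simulate_panel()] result for replicate `i`.
#' @export
realise_replicate <- function(suite, i) {
  stopifnot(inherits(suite, "recovery_suite"),
            i >= 1, i <= suite$n_replicates)
  cfg <- suite$config
  cfg$seed <- suite$seeds[i]
  simulate_panel(cfg)
}

#' Bias and coverage over a recovery suite
#'
#' Fits the model to each replicate and tabulates, per parameter, the mean
#' estimate, the bias against the generating truth, the Monte-Carlo
#' standard error of the mean estimate, and the empirical coverage of
#' nominal 95% Wald intervals.
#'
#' @param suite A `recovery_suite`.
#' @param covariates Covariates passed to [fit_msm()].
#' @param vcov_type Covariance used for the intervals (default
#'   `"sandwich"`, appropriate under variable survey weights).
#' @param conf Nominal interval level.
#' @return data.frame: `parameter`, `truth`, `mean_est`, `bias`,
#'   `mc_se`, `coverage`, `n_replicates`.
#' @export
recovery_summary <- function(suite, covariates = NULL,
                             vcov_type = c("sandwich", "model"),
                             conf = 0.95) {
  vcov_type <- match.arg(vcov_type)
  truth_par <- .pack(suite$config$truth)
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  ests <- ses <- NULL
  for (i in seq_len(suite$n_replicates)) {
    rep_i <- realise_replicate(suite, i)
    fit <- fit_msm(rep_i$panel, suite$config$truth$struct,
                   covariates = covariates)
    ests <- rbind(ests, fit$estimates)
    ses <- rbind(ses, sqrt(diag(vcov(fit, vcov_type))))
  }
  covered <- abs(sweep(ests, 2, truth_par)) <= zq * ses
  data.frame(
    parameter = colnames(ests),
    truth = truth_par,
    mean_est = colMeans(ests),
    bias = colMeans(ests) - truth_par,
    mc_se = apply(ests, 2, stats::sd) / sqrt(nrow(ests)),
    coverage = colMeans(covered),
    n_replicates = suite$n_replicates,
    row.names = NULL, stringsAsFactors = FALSE
  )
}
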