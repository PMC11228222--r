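ECIG_RESPONSES_MULTI <- c("never", "tried once or twice", "past not now",
                          "less than monthly", "monthly not weekly",
                          "at least weekly")
ECIG_RESPONSES_BINARY <- c("yes", "no")

#' Code current e-cigarette use from a questionnaire response
#'
#' Wave 7 of the survey asked a binary question ("Do you ever use electronic
#' cigarettes", yes/no); waves 8-12 used six response categories. A
#' respondent is a current e-cigarette user for every response except
#' "never" and "past not now" (wave 7: a "yes").
#'
#' @param ecig_response Character vector of responses.
#' @param wave Integer vector of wave indices (7-12), recycled.
#' @return Logical vector of current-use flags; `NA` responses give `NA`.
#' @export
#' @examples
#' code_ecig_current("tried once or twice", 9)  # TRUE
#' code_ecig_current("past not now", 9)         # FALSE
code_ecig_current <- function(ecig_response, wave) {
  n <- max(length(ecig_response), length(wave))
  ecig_response <- rep_len(as.character(ecig_response), n)
  wave <- rep_len(as.integer(wave), n)
  if (any(!wave %in% 7:12, na.rm = TRUE)) {
    stop("wave must be in 7-12; got ",
         paste(unique(wave[!wave %in% 7:12]), collapse = ", "))
  }
  out <- rep(NA, n)
  binary <- wave == 7
  ok_bin <- ecig_response %in% ECIG_RESPONSES_BINARY | is.na(ecig_response)
  ok_mult <- ecig_response %in% ECIG_RESPONSES_MULTI | is.na(ecig_response)
  bad <- (binary & !ok_bin) | (!binary & !ok_mult)
  if (any(bad)) {
    i <- which(bad)[1]
    stop("e-cigarette response '", ecig_response[i],
         "' is not valid for wave ", wave[i])
  }
  out[binary] <- ecig_response[binary] == "yes"
  out[!binary] <- !(ecig_response[!binary] %in% c("never", "past not now"))
  out[is.na(ecig_response)] <- NA
  out
}

#' Code current cigarette smoking from a questionnaire response
#'
#' @param smoke_response Character vector, `"yes"` or `"no"`.
#' @return Logical vector; `NA` gives `NA`.
#' @export
code_smoking_current <- function(smoke_response) {
  smoke_response <- as.character(smoke_response)
  bad <- !(smoke_response %in% c("yes", "no")) & !is.na(smoke_response)
  if (any(bad)) {
    stop("smoking response must be 'yes' or 'no'; got '",
         smoke_response[which(bad)[1]], "'")
  }
  smoke_response == "yes"
}

#' Derive the nicotine product use state at one observation
#'
#' Applies the four-state definition: current smokers (including dual users)
#' are `SMOKING`; otherwise current e-cigarette users are `ECIG_ONLY`;
#' otherwise respondents with established prior use are `NONCURRENT`;
#' otherwise `NEVER` -- except that a non-using respondent at their first
#' observation aged 16 or over answers only current-use questions, so never
#' use cannot be established and they are classified `NONCURRENT` with
#' `assumed_noncurrent = TRUE` (the flag drives a dedicated sensitivity
#' analysis). The 10-15 questionnaire asks about ever use, which does
#' establish never use for younger respondents.
#'
#' @param ecig_current,smoking_current Logical current-use flags.
#' @param any_prior_use_observed Logical: ever-use established by this or
#'   any earlier wave (earlier current use, or a "past not now" response).
#' @param is_first_observation Logical: is this the subject's first record.
#' @param age_years Integer age at the observation.
#' @return data.frame with columns `state` (character) and
#'   `assumed_noncurrent` (logical).
#' @export
derive_state <- function(ecig_current, smoking_current,
                         any_prior_use_observed, is_first_observation,
                         age_years) {
  n <- max(length(ecig_current), length(smoking_current),
           length(any_prior_use_observed), length(is_first_observation),
           length(age_years))
  ecig_current <- rep_len(ecig_current, n)
  smoking_current <- rep_len(smoking_current, n)
  any_prior_use_observed <- rep_len(any_prior_use_observed, n)
  is_first_observation <- rep_len(is_first_observation, n)
  age_years <- rep_len(age_years, n)

  state <- rep(NA_character_, n)
  assumed <- rep(FALSE, n)
  state[smoking_current] <- "SMOKING"
  idx <- !smoking_current & ecig_current
  state[idx] <- "ECIG_ONLY"
  nonuser <- !smoking_current & !ecig_current
  state[nonuser & any_prior_use_observed] <- "NONCURRENT"
  unknown <- nonuser & !any_prior_use_observed
  assumed_idx <- unknown & is_first_observation & age_years >= 16
  state[assumed_idx] <- "NONCURRENT"
  assumed[assumed_idx] <- TRUE
  state[unknown & !assumed_idx] <- "NEVER"
  data.frame(state = state, assumed_noncurrent = assumed,
             stringsAsFactors = FALSE)
}

#' Equivalise household income for household composition
#'
#' Divides net monthly household income by an OECD equivalence factor. The
#' default is the modified OECD scale (first adult 1.0, each further adult
#' 0.5, each child under 14 years 0.3), the convention used for UK
#' household panel income variables; the original OECD scale (1.0/0.7/0.5)
#' is selectable.
#'
#' @param household_income_monthly Numeric, currency per month.
#' @param adults Number of adults (>= 1).
#' @param children_under14 Number of children under 14 (>= 0).
#' @param scale `"modified"` (default) or `"original"`.
#' @return Equivalised income, currency per month.
#' @export
#' @examples
#' equivalise_income(1800, 2, 0)  # 1200
#' equivalise_income(2160, 2, 2)  # 2160 / 2.1
equivalise_income <- function(household_income_monthly, adults,
                              children_under14,
                              scale = c("modified", "original")) {
  scale <- match.arg(scale)
  if (any(adults < 1, na.rm = TRUE)) {
    stop("household must contain at least one adult")
  }
  if (any(children_under14 < 0, na.rm = TRUE)) stop("negative child count")
  if (any(household_income_monthly < 0, na.rm = TRUE)) {
    stop("negative household income")
  }
  w <- if (scale == "modified") c(0.5, 0.3) else c(0.7, 0.5)
  factor <- 1 + w[1] * (adults - 1) + w[2] * children_under14
  household_income_monthly / factor
}

#' Default equivalised-income tertile cutoffs (GBP/month)
#'
#' Tertile boundaries of equivalised net monthly household income used for
#' the income covariate: low below 1191, mid from 1191 to 1787 inclusive,
#' high above 1787.
#' @return Numeric vector of the two cutoffs.
#' @export
income_tertile_cutoffs <- function() c(low_mid = 1191, mid_high = 1787)

#' Assign covariate bands
#'
#' Categorises age into the four analysis bands (10-13, 14-17, 18-21,
#' 22-25) and equivalised income into tertiles at the published cutoffs
#' (both boundaries belong to the mid band). Factors carry the model
#' reference level first: age 14-17, female, white, low income.
#'
#' @param age_years Integer ages, 10-25.
#' @param sex Character, `"male"` / `"female"`.
#' @param ethnicity Character, `"white"` / `"ethnic minority"`.
#' @param equivalised_income Numeric, currency per month.
#' @param cutoffs Two tertile cutoffs, see [income_tertile_cutoffs()].
#' @return data.frame with factor columns `age_band`, `sex`, `ethnicity`,
#'   `income_tertile`.
#' @export
assign_covariate_bands <- function(age_years, sex, ethnicity,
                                   equivalised_income,
                                   cutoffs = income_tertile_cutoffs()) {
  if (any(age_years < 10 | age_years > 25, na.rm = TRUE)) {
    stop("age out of the 10-25 study range: ",
         paste(utils::head(unique(
       age_years[age_years < 10 | age_years > 25]), 5), collapse = ", "))
  }
  age_band <- cut(age_years, breaks = c(9, 13, 17, 21, 25),
                  labels = c("10-13", "14-17", "18-21", "22-25"))
  age_band <- factor(age_band,
                     levels = c("14-17", "10-13", "18-21", "22-25"))
  income_tertile <- ifelse(equivalised_income < cutoffs[1], "low",
                    ifelse(equivalised_income <= cutoffs[2], "mid", "high"))
  data.frame(
    age_band = age_band,
    sex = factor(sex, levels = c("female", "male")),
    ethnicity = factor(ethnicity, levels = c("white", "ethnic minority")),
    income_tertile = factor(income_tertile,
                            levels = c("low", "mid", "high")),
    stringsAsFactors = FALSE
  )
}

#' Code a raw questionnaire panel into the analysis panel
#'
#' Full coding flow for a long-format raw panel (one row per subject-wave;
#' see the packaged data dictionary): codes current-use flags from the
#' wave-appropriate response formats, tracks ever-use history within
#' subject, derives the four-state classification including the
#' assumed-non-current rule, equivalises income and assigns covariate
#' bands, and applies the exclusion flow: records with missing nicotine
#' responses are dropped, subjects with missing ethnicity or income are
#' dropped entirely, and subjects observed at fewer than two retained waves
#' are dropped.
#'
#' Ever use counts as established at a wave if the subject was a current
#' user at any earlier retained wave, or answered "past not now" at this or
#' any earlier wave (waves 8-12 only; the wave-7 binary question carries no
#' history information).
#'
#' @param raw data.frame in the raw-record schema (see
#'   `system.file("extdata", "data_dictionary.md", package = "nicomsm")`).
#' @param oecd_scale Equivalence scale, `"modified"` or `"original"`.
#' @param cutoffs Income tertile cutoffs.
#' @return Coded panel data.frame: `subject_id`, `time`, `wave`, `state`,
#'   `age_years`, `age_band`, `sex`, `ethnicity`, `income_tertile`,
#'   `weight`, `assumed_noncurrent` (plus `interview_date` when present),
#'   ordered by subject and time.
#' @export
code_panel <- function(raw, oecd_scale = c("modified", "original"),
                       cutoffs = income_tertile_cutoffs()) {
  oecd_scale <- match.arg(oecd_scale)
  req <- c("subject_id", "wave", "interview_time", "age_years",
           "ecig_response", "smoke_response", "sex", "ethnicity",
           "household_income_monthly", "household_adults",
           "household_children_under14", "survey_weight")
  miss <- setdiff(req, names(raw))
  if (length(miss)) stop("raw panel missing columns: ",
                         paste(miss, collapse = ", "))
  raw <- raw[order(raw$subject_id, raw$interview_time), , drop = FALSE]

  ecig <- code_ecig_current(raw$ecig_response, raw$wave)
  smoke <- code_smoking_current(raw$smoke_response)
  keep <- !is.na(ecig) & !is.na(smoke)
  raw <- raw[keep, , drop = FALSE]
  ecig <- ecig[keep]; smoke <- smoke[keep]

  # subjects with missing ethnicity or income are excluded entirely
  bad_cov <- is.na(raw$ethnicity) | is.na(raw$household_income_monthly)
  bad_subj <- unique(raw$subject_id[bad_cov])
  keep <- !(raw$subject_id %in% bad_subj)
  raw <- raw[keep, , drop = FALSE]
  ecig <- ecig[keep]; smoke <- smoke[keep]

  # within-subject ever-use history (monotone once observed). An
  # assumed-non-current first observation (non-user aged >= 16 whose
  # questionnaire cannot establish never use) also fixes the history so
  # later non-use waves stay non-current rather than reverting to never.
  sid <- raw$subject_id
  first <- !duplicated(sid)
  current_use <- ecig | smoke
  past_resp <- raw$ecig_response == "past not now" & raw$wave != 7
  assumed_first <- first & !current_use & !past_resp & raw$age_years >= 16
  any_prior <- logical(nrow(raw))
  hist_flag <- FALSE
  for (i in seq_len(nrow(raw))) {
    if (first[i]) hist_flag <- FALSE
    any_prior[i] <- hist_flag || past_resp[i]
    hist_flag <- hist_flag || past_resp[i] || current_use[i] ||
      assumed_first[i]
  }

  st <- derive_state(ecig, smoke, any_prior, first, raw$age_years)
  eq_inc <- equivalise_income(raw$household_income_monthly,
                              raw$household_adults,
                              raw$household_children_under14,
                              scale = oecd_scale)
  bands <- assign_covariate_bands(raw$age_years, raw$sex, raw$ethnicity,
                                  eq_inc, cutoffs)

  out <- data.frame(
    subject_id = raw$subject_id,
    time = raw$interview_time,
    wave = raw$wave,
    state = st$state,
    age_years = raw$age_years,
    stringsAsFactors = FALSE
  )
  out <- cbind(out, bands)
  out$weight <- raw$survey_weight
  out$assumed_noncurrent <- st$assumed_noncurrent
  if ("interview_date" %in% names(raw)) {
    out$interview_date <- as.Date(raw$interview_date)
  }
  drop_singletons(out)
}

#' Drop subjects observed fewer than two times
#'
#' The interval-censored likelihood needs at least one within-subject
#' observation pair, so single-wave subjects carry no information and are
#' excluded, mirroring the study inclusion rule.
#'
#' @param panel Coded panel data.frame with a `subject_id` column.
#' @return The panel restricted to subjects with two or more rows.
#' @export
drop_singletons <- function(panel) {
  n_obs <- table(panel$subject_id)
  keep <- panel$subject_id %in% names(n_obs)[n_obs >= 2]
  out <- panel[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
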