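test_that("e-cigarette coding follows the wave-specific response formats", {
  # six-category waves: everything except never / past-not-now is current
  expect_true(code_ecig_current("tried once or twice", 9))
  expect_true(code_ecig_current("less than monthly", 8))
  expect_true(code_ecig_current("monthly not weekly", 12))
  expect_true(code_ecig_current("at least weekly", 10))
  expect_false(code_ecig_current("never", 9))
  expect_false(code_ecig_current("past not now", 9))
  # binary wave
  expect_true(code_ecig_current("yes", 7))
  expect_false(code_ecig_current("no", 7))
  # domain errors name the wave and the response
  expect_error(code_ecig_current("yes", 9), "wave 9")
  expect_error(code_ecig_current("never", 7), "never")
  expect_error(code_ecig_current("no", 13), "wave")
  # missing propagates (records excluded upstream)
  expect_true(is.na(code_ecig_current(NA, 9)))
})

test_that("smoking coding accepts only yes/no and propagates missing", {
  expect_equal(code_smoking_current(c("yes", "no", NA)),
               c(TRUE, FALSE, NA))
  expect_error(code_smoking_current("sometimes"), "yes")
})

test_that("state derivation maps every flag combination to one state", {
  cases <- expand.grid(ecig = c(TRUE, FALSE), smoke = c(TRUE, FALSE),
                       prior = c(TRUE, FALSE), first = c(TRUE, FALSE),
                       age = c(12L, 17L))
  got <- derive_state(cases$ecig, cases$smoke, cases$prior, cases$first,
                      cases$age)
  expect_false(anyNA(got$state))
  # smoking dominates (dual users are smokers)
  expect_true(all(got$state[cases$smoke] == "SMOKING"))
  # e-cig only when not smoking
  expect_true(all(got$state[!cases$smoke & cases$ecig] == "ECIG_ONLY"))
  # established prior use -> non-current
  expect_true(all(
    got$state[!cases$smoke & !cases$ecig & cases$prior] == "NONCURRENT"))
  # the assumed-non-current rule: first observation, 16+, nothing known
  unk <- !cases$smoke & !cases$ecig & !cases$prior
  assumed <- unk & cases$first & cases$age >= 16
  expect_true(all(got$state[assumed] == "NONCURRENT"))
  expect_true(all(got$assumed_noncurrent[assumed]))
  expect_true(all(got$state[unk & !assumed] == "NEVER"))
  expect_false(any(got$assumed_noncurrent[!assumed]))
})

test_that("income equivalisation matches both OECD scales", {
  expect_equal(equivalise_income(1000, 1, 0), 1000)
  expect_equal(equivalise_income(1800, 2, 0), 1200)
  # independent hand computation: factor 1 + 0.5 + 2 * 0.3 = 2.1
  expect_equal(equivalise_income(2160, 2, 2), 2160 / 2.1,
               tolerance = 1e-12)
  # original scale: factor 1 + 0.7 + 2 * 0.5 = 2.7
  expect_equal(equivalise_income(2160, 2, 2, scale = "original"),
               2160 / 2.7, tolerance = 1e-12)
  expect_error(equivalise_income(1000, 0, 0), "adult")
})

test_that("covariate bands use the published cutoffs and closed mid band", {
  b <- assign_covariate_bands(c(10, 14, 18, 25), rep("male", 4),
                              rep("white", 4),
                              c(1190, 1191, 1787, 1788))
  expect_equal(as.character(b$age_band),
               c("10-13", "14-17", "18-21", "22-25"))
  expect_equal(as.character(b$income_tertile),
               c("low", "mid", "mid", "high"))
  # reference levels come first for modelling
  expect_equal(levels(b$age_band)[1], "14-17")
  expect_equal(levels(b$sex)[1], "female")
  expect_equal(levels(b$ethnicity)[1], "white")
  expect_equal(levels(b$income_tertile)[1], "low")
  expect_error(assign_covariate_bands(26, "male", "white", 1000), "age")
})

test_that("full coding flow applies state, history and exclusion rules", {
  coded <- code_panel(raw_fixture())

  # r4's missing-response record is dropped but the subject is kept;
  # r5 (missing ethnicity) and r6 (single wave) are gone entirely
  expect_setequal(unique(coded$subject_id), c("r1", "r2", "r3", "r4"))
  expect_equal(nrow(coded[coded$subject_id == "r4", ]), 2)

  # r1: never -> e-cig -> non-current (history established by use)
  r1 <- coded[coded$subject_id == "r1", ]
  expect_equal(r1$state, c("NEVER", "ECIG_ONLY", "NONCURRENT"))
  expect_false(any(r1$assumed_noncurrent))

  # r2: assumed non-current at 17 (flagged), then smoking
  r2 <- coded[coded$subject_id == "r2", ]
  expect_equal(r2$state, c("NONCURRENT", "SMOKING"))
  expect_equal(r2$assumed_noncurrent, c(TRUE, FALSE))

  # r3: young never user throughout (ever-use question establishes it)
  expect_equal(coded$state[coded$subject_id == "r3"],
               c("NEVER", "NEVER"))

  # flagged count equals the analytic expectation: first observations at
  # age >= 16 with both flags false and no history information
  expect_equal(sum(coded$assumed_noncurrent), 1)

  # income tertile from equivalised income: 1500 / (1 + 0.5 + 0.3)
  expect_true(all(coded$income_tertile == "low"))
})

test_that("never use cannot recur after any non-never state", {
  # property over a simulated, response-emulated panel
  cfg <- sim_config(n_subjects = 300, first_wave = 8, n_waves = 5,
                    emulate_responses = TRUE, seed = 99)
  sim <- simulate_panel(cfg)
  coded <- code_panel(sim$raw)
  bad <- vapply(split(coded$state, coded$subject_id), function(s) {
    seen <- cumsum(s != "NEVER") > 0
    any(s == "NEVER" & c(FALSE, seen[-length(seen)]))
  }, logical(1))
  expect_false(any(bad))
})
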