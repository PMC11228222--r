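test_that("interval log-likelihood matches the two-state closed form", {
  lam <- 0.3
  m <- two_state_model(lam)
  dt <- 1.7
  expect_equal(interval_log_likelihood(m, "A", "B", dt),
               log(1 - exp(-lam * dt)), tolerance = 1e-12)
  expect_equal(interval_log_likelihood(m, "A", "A", dt), -lam * dt,
               tolerance = 1e-12)
})

test_that("impossible observed pairs give -Inf with an identifying warning", {
  m <- default_truth_model()
  expect_warning(
    ll <- interval_log_likelihood(m, "NONCURRENT", "NEVER", 1),
    "NONCURRENT->NEVER"
  )
  expect_identical(ll, -Inf)
  # and at the panel level
  bad <- data.frame(subject_id = c("x", "x"), time = c(0, 1),
                    state = c("SMOKING", "NEVER"), weight = 1)
  expect_warning(ll2 <- weighted_log_likelihood(m, bad),
                 "SMOKING->NEVER")
  expect_identical(ll2, -Inf)
})

test_that("interval probabilities agree with the series oracle", {
  set.seed(4)
  struct <- transition_structure()
  for (i in 1:5) {
    Q <- random_valid_Q(struct)
    m <- intensity_model(struct,
                         log(Q[cbind(struct$arrows$from,
                                     struct$arrows$to)]))
    dt <- runif(1, 0.5, 2)
    Pser <- expm_series(Q, dt)
    for (pair in list(c("NEVER", "ECIG_ONLY"),
                      c("ECIG_ONLY", "SMOKING"),
                      c("SMOKING", "SMOKING"))) {
      expect_equal(interval_log_likelihood(m, pair[1], pair[2], dt),
                   log(Pser[pair[1], pair[2]]), tolerance = 1e-8)
    }
  }
})

test_that("weighted log-likelihood matches a hand-computed fixture sum", {
  panel <- tiny_panel()
  m <- default_truth_model()
  Q <- build_Q(m)
  # four intervals; subject weights 2 and 1 rescale to 4/3 and 2/3
  P1 <- expm_series(Q, 1); P15 <- expm_series(Q, 1.5)
  P2 <- expm_series(Q, 2)
  by_hand <- (4 / 3) * (log(P1["NEVER", "ECIG_ONLY"]) +
                          log(P15["ECIG_ONLY", "SMOKING"])) +
    (2 / 3) * (log(P2["NEVER", "NEVER"]) +
                 log(P1["NEVER", "ECIG_ONLY"]))
  expect_equal(weighted_log_likelihood(m, panel), by_hand,
               tolerance = 1e-8)
  # equal weights equal the unweighted value after mean-1 rescaling
  p_eq <- panel; p_eq$weight <- 5
  p_un <- panel; p_un$weight <- NULL
  expect_equal(weighted_log_likelihood(m, p_eq),
               weighted_log_likelihood(m, p_un), tolerance = 1e-12)
})

test_that("duplicating a subject equals doubling its weight (no rescale)", {
  panel <- tiny_panel()
  m <- default_truth_model()
  dup <- panel[panel$subject_id == "b", ]
  dup$subject_id <- "b2"
  ll_dup <- weighted_log_likelihood(m, rbind(panel, dup),
                                    rescale_weights = FALSE)
  dbl <- panel
  dbl$weight[dbl$subject_id == "b"] <- 2
  ll_dbl <- weighted_log_likelihood(m, dbl, rescale_weights = FALSE)
  expect_equal(ll_dup, ll_dbl, tolerance = 1e-12)
})

test_that("covariate-free likelihood equals zero-beta adjusted likelihood", {
  cfg <- sim_config(n_subjects = 150, seed = 5)
  sim <- simulate_panel(cfg)
  struct <- transition_structure()
  m0 <- default_truth_model()
  beta <- matrix(0, 8, 2,
                 dimnames = list(NULL, c("sexmale",
                                         "ethnicityethnic minority")))
  mz <- intensity_model(struct, m0$log_baseline, beta)
  expect_equal(
    weighted_log_likelihood(mz, sim$panel,
                            covariates = c("sex", "ethnicity")),
    weighted_log_likelihood(m0, sim$panel),
    tolerance = 1e-10
  )
})

test_that("crude initial rates match a hand tally and floor empty arrows", {
  panel <- tiny_panel()
  init <- crude_initial_rates(panel)
  r <- exp(init$log_baseline)
  # hand tally with mean-1 rescaled weights 4/3 (a) and 2/3 (b):
  # NEVER person-time 4/3*1 + 2/3*2 + 2/3*1 = 10/3;
  # NEVER->ECIG patterns 4/3 + 2/3 = 2 -> rate 0.6
  expect_equal(unname(r["NEVER->ECIG_ONLY"]), 0.6, tolerance = 1e-12)
  # ECIG person-time 4/3*1.5 = 2; ECIG->SMOKING patterns 4/3 -> 2/3
  expect_equal(unname(r["ECIG_ONLY->SMOKING"]), 2 / 3,
               tolerance = 1e-12)
  # unobserved arrows sit at the floor
  expect_equal(unname(r["SMOKING->NONCURRENT"]), 1e-4)
  # single subject, one 1-year interval: rate 1 before flooring
  p1 <- data.frame(subject_id = "s", time = c(0, 1),
                   state = c("NONCURRENT", "ECIG_ONLY"), weight = 1)
  expect_equal(unname(exp(crude_initial_rates(
    p1)$log_baseline)["NONCURRENT->ECIG_ONLY"]), 1, tolerance = 1e-12)
})

test_that("fitting recovers the generating intensities on synthetic data", {
  sf <- shared_sim_fit()
  fit <- sf$fit
  truth <- sf$sim$truth$log_baseline
  se <- sqrt(diag(vcov(fit, "sandwich")))
  z <- (fit$model$log_baseline - truth) / se
  expect_true(all(abs(z) < 4))
  expect_true(fit$convergence)
  expect_lt(fit$gradient_norm / abs(fit$loglik), 1e-4)
})

test_that("weight-scale invariance of fitted point estimates", {
  cfg <- sim_config(n_subjects = 500, seed = 6)
  sim <- simulate_panel(cfg)
  f1 <- fit_msm(sim$panel)
  p2 <- sim$panel
  p2$weight <- p2$weight * 1000
  f2 <- fit_msm(p2)
  expect_equal(f1$estimates, f2$estimates, tolerance = 1e-6)
  # and model-based standard errors agree after the mean-1 rescaling
  expect_equal(sqrt(diag(f1$vcov_model)), sqrt(diag(f2$vcov_model)),
               tolerance = 1e-4)
})

test_that("a state with no observed exits drifts to the zero boundary", {
  set.seed(8)
  # subjects that never leave SMOKING plus a few NEVER->ECIG movers
  panel <- rbind(
    data.frame(subject_id = rep(sprintf("s%02d", 1:20), each = 3),
               time = rep(0:2, 20),
               state = "SMOKING", weight = 1),
    data.frame(subject_id = rep(sprintf("n%02d", 1:20), each = 3),
               time = rep(0:2, 20),
               state = rep(c("NEVER", "NEVER", "ECIG_ONLY"), 20),
               weight = 1)
  )
  w <- capture_warnings(fit <- fit_msm(panel,
                                       control = list(maxit = 200)))
  expect_true(any(grepl("no observed interval pattern", w)))
  expect_true(any(grepl("zero boundary", w)))
  # the unexercised exit intensities sit at (or near) the floor
  expect_lt(min(exp(fit$model$log_baseline)), 1e-4 + 1e-10)
})

test_that("structure/data mismatch is a fitting error, not a silent -Inf", {
  bad <- data.frame(
    subject_id = rep(c("x", "y"), each = 2), time = rep(c(0, 1), 2),
    state = c("SMOKING", "NEVER", "NEVER", "ECIG_ONLY"), weight = 1)
  expect_error(fit_msm(bad), "impossible under the permitted structure")
})

test_that("hazard ratios exponentiate coefficients with Wald intervals", {
  sf <- shared_sim_fit()
  # refit a small adjusted model on a subset for speed
  panel <- sf$sim$panel
  keep <- unique(panel$subject_id)[1:800]
  fit <- suppressWarnings(
    fit_msm(panel[panel$subject_id %in% keep, ], covariates = "sex"))
  hr <- hazard_ratios(fit)
  expect_equal(nrow(hr), 8)
  expect_equal(hr$HR, exp(hr$log_hr))
  expect_equal(hr$lo, exp(hr$log_hr - qnorm(0.975) * hr$se))
  expect_true(all(hr$lo <= hr$HR & hr$HR <= hr$hi))
})
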