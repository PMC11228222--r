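test_that("intensity-matrix validation reports offending entries", {
  Q <- rbind(c(-1, 1), c(0.5, -0.5))
  expect_silent(validate_intensity_matrix(Q))
  Qbad <- rbind(c(-1, 1), c(-0.2, 0.2))
  expect_error(validate_intensity_matrix(Qbad), "negative off-diagonal")
  Qbad2 <- rbind(c(-1, 1.5), c(0, 0))
  expect_error(validate_intensity_matrix(Qbad2), "row 1 sums")
  # an arrow outside the permitted structure is flagged by name
  struct <- transition_structure()
  Q4 <- random_valid_Q(struct)
  Q4["NONCURRENT", "NEVER"] <- 0.1
  Q4["NONCURRENT", "NONCURRENT"] <-
    Q4["NONCURRENT", "NONCURRENT"] - 0.1
  expect_error(validate_intensity_matrix(Q4, struct),
               "NONCURRENT->NEVER")
})

test_that("transition probabilities match closed forms and the series oracle", {
  # t = 0 gives the identity
  Q <- random_valid_Q()
  expect_equal(transition_probability(Q, 0), diag(4) + 0 * Q,
               ignore_attr = TRUE)
  # one-way two-state chain: P[1,2](t) = 1 - exp(-lambda t)
  lam <- 0.5
  Q2 <- rbind(c(-lam, lam), c(0, 0))
  expect_equal(transition_probability(Q2, 2)[1, 2], 1 - exp(-1),
               tolerance = 1e-10)
  # random 4-state generators against the 60-term truncated series
  set.seed(1)
  for (i in 1:10) {
    Q <- random_valid_Q()
    expect_equal(transition_probability(Q, 1), expm_series(Q, 1),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("Chapman-Kolmogorov and time-homogeneity consistency hold", {
  set.seed(2)
  for (i in 1:20) {
    Q <- random_valid_Q()
    s <- runif(1, 0.2, 2)
    t <- runif(1, 0.2, 2)
    lhs <- transition_probability(Q, s + t)
    rhs <- transition_probability(Q, s) %*% transition_probability(Q, t)
    expect_lt(max(abs(lhs - rhs)), 1e-8)
    # iterating P(1) annually equals P(k) directly
    k <- sample(2:6, 1)
    expect_lt(max(abs(iterate_annual(transition_probability(Q, 1), k) -
                        transition_probability(Q, k))), 1e-8)
  }
})

test_that("the never-user survival probability is non-increasing in time", {
  set.seed(3)
  Q <- random_valid_Q()
  p <- vapply(seq(0, 6, by = 0.25), function(t)
    transition_probability(Q, t)["NEVER", "NEVER"], numeric(1))
  expect_true(all(diff(p) <= 1e-12))
})

test_that("printed-matrix normalisation fixes rounded rows and keeps provenance", {
  raw <- rbind(c(79.6, 12.2, 8.3), c(10, 80, 10), c(0, 0, 100))
  P <- normalise_printed(raw)
  expect_equal(rowSums(P), rep(1, 3))
  expect_equal(attr(P, "raw"), raw)
  # an already-stochastic row is unchanged
  expect_equal(P[2, ], c(0.1, 0.8, 0.1))
  expect_error(normalise_printed(rbind(c(-1, 2), c(1, 1))), "negative")
  expect_error(normalise_printed(rbind(c(0, 0), c(1, 1))), "zero row")
})

test_that("iterate_annual rejects non-stochastic input and k=0 is identity", {
  P <- normalise_printed(reference_one_year_matrix())
  expect_equal(iterate_annual(P, 0), diag(4), ignore_attr = TRUE)
  expect_error(iterate_annual(reference_one_year_matrix() / 100, 2),
               "renormalise")
})

test_that("occupancy curves are distributions and absorb correctly", {
  # absorbing toy chain: once in state B, occupancy is constant
  P <- rbind(c(0.5, 0.5), c(0, 1))
  dimnames(P) <- list(c("A", "B"), c("A", "B"))
  occ <- occupancy_curve(P, "B", 4)
  expect_equal(occ$B, rep(1, 4))
  occA <- occupancy_curve(P, "A", 5)
  expect_equal(rowSums(occA[, -1]), rep(1, 5))
  expect_equal(occA$A, 0.5^(1:5))
  expect_error(occupancy_curve(P, "C", 3), "unknown starting state")
})

test_that("matrix CSV round-trips with state labels", {
  M <- normalise_printed(reference_one_year_matrix())
  attr(M, "raw") <- NULL
  f <- tempfile(fileext = ".csv")
  write_matrix_csv(M, f)
  expect_equal(read_matrix_csv(f), M)
})

test_that("structure JSON round-trips and validation catches bad arrows", {
  st <- transition_structure()
  f <- tempfile(fileext = ".json")
  write_structure_json(st, f)
  st2 <- read_structure_json(f)
  expect_equal(st2$states, st$states)
  expect_equal(st2$arrows, st$arrows)
  expect_error(transition_structure(arrows = data.frame(
    from = "NEVER", to = "NEVER")), "self-arrows")
  expect_error(transition_structure(arrows = data.frame(
    from = "NEVER", to = "QUIT")), "unknown states")
})
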