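#' Fitted one-year transition matrix
#'
#' The one-year transition-probability matrix implied by a fitted model at
#' a given covariate pattern (default: the reference pattern, i.e. the
#' unadjusted matrix when the fit is covariate-free).
#'
#' @param fit A `nicomsm_fit`.
#' @param z Named covariate dummy vector, or `NULL` for reference.
#' @return Row-stochastic 4x4 matrix.
#' @export
fitted_one_year <- function(fit, z = NULL) {
  stopifnot(inherits(fit, "nicomsm_fit"))
  transition_probability(build_Q(fit$model, z), 1)
}

# draw from N(mean, V) allowing positive semi-definite V
.rmvnorm <- function(n, mean, V) {
  eg <- eigen(V, symmetric = TRUE)
  lam <- eg$values
  tol <- 1e-8 * max(abs(lam), 1)
  if (any(lam < -tol)) {
    stop("covariance matrix is not positive semi-definite; try the other ",
         "covariance type ('model' vs 'sandwich')")
  }
  lam[lam < 0] <- 0
  A <- eg$vectors %*% (t(eg$vectors) * sqrt(lam))
  mean <- as.numeric(mean)
  t(mean + A %*% matrix(stats::rnorm(n * length(mean)), length(mean), n))
}

#' Parametric-bootstrap percentile intervals for a model functional
#'
#' Draws parameter vectors from the fit's asymptotic normal distribution,
#' recomputes an arbitrary functional of the intensity model for each
#' draw, and returns pointwise percentile intervals. Seeded and
#' reproducible.
#'
#' @param fit A converged `nicomsm_fit` with a valid covariance.
#' @param functional Function taking an `intensity_model` and returning a
#'   numeric vector/matrix/array (constant shape across draws).
#' @param B Number of bootstrap draws (default 1000).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @param vcov_type `"model"` or `"sandwich"`.
#' @return List with `point`, `lo`, `hi` (same shape as the functional's
#'   value), and `B`.
#' @export
bootstrap_intervals <- function(fit, functional, B = 1000, seed = 1,
                                conf = 0.95,
                                vcov_type = c("model", "sandwich")) {
  stopifnot(inherits(fit, "nicomsm_fit"), B >= 1)
  vcov_type <- match.arg(vcov_type)
  V <- vcov(fit, vcov_type)
  if (anyNA(V)) stop("fit has no valid ", vcov_type, " covariance")
  point <- functional(fit$model)
  skel <- list(struct = fit$struct, terms = fit$terms)
  set.seed(seed)
  draws <- .rmvnorm(B, fit$estimates, V)
  vals <- vapply(seq_len(B), function(b) {
    m <- .unpack(draws[b, ], skel)
    as.numeric(functional(m))
  }, numeric(length(point)))
  vals <- matrix(vals, nrow = length(point))
  a <- (1 - conf) / 2
  lo <- apply(vals, 1, stats::quantile, probs = a, names = FALSE)
  hi <- apply(vals, 1, stats::quantile, probs = 1 - a, names = FALSE)
  shape <- function(v) {
    out <- point
    out[] <- v
    out
  }
  list(point = point, lo = shape(lo), hi = shape(hi), B = B)
}

# resolve a projection source into a one-year matrix (+ optional fit)
.resolve_source <- function(source) {
  if (inherits(source, "nicomsm_fit")) {
    list(P1 = fitted_one_year(source), fit = source,
         provenance = "fitted model")
  } else if (is.matrix(source)) {
    list(P1 = normalise_printed(source), fit = NULL,
         provenance = "printed matrix (row-normalised)")
  } else {
    stop("source must be a nicomsm_fit or a matrix")
  }
}

#' One-year transition probability table
#'
#' The 4x4 one-year transition probabilities as percentages, with
#' parametric-bootstrap intervals when the source is a fitted model
#' (intervals are absent for a printed-matrix source, which is simply
#' row-normalised and echoed).
#'
#' @param source A `nicomsm_fit`, or a printed matrix of probabilities /
#'   percentages.
#' @param B,seed,vcov_type Bootstrap settings (fitted source only).
#' @return Object of class `nicomsm_projection` at horizon 1 (percent
#'   scale): `point`, `lo`, `hi`, `provenance`.
#' @export
one_year_table <- function(source, B = 1000, seed = 1,
                           vcov_type = c("model", "sandwich")) {
  project(source, k = 1, B = B, seed = seed, vcov_type = vcov_type)
}

#' Multi-year transition probability projection
#'
#' Raises the one-year transition matrix to the k-th power, each iteration
#' corresponding to one year. For a fitted source, pointwise percentile
#' intervals come from a parametric bootstrap over the fit's asymptotic
#' normal; `k = 0` returns the identity with degenerate intervals.
#'
#' @inheritParams one_year_table
#' @param k Horizon in whole years (`k >= 0`).
#' @return Object of class `nicomsm_projection`: percent-scale `point`,
#'   `lo`, `hi` matrices, `k`, `B`, `provenance`.
#' @export
#' @examples
#' P1 <- reference_one_year_matrix()
#' round(project(P1, 3)$point)  # three-year percentages
project <- function(source, k, B = 1000, seed = 1,
                    vcov_type = c("model", "sandwich")) {
  stopifnot(length(k) == 1, k >= 0, k == round(k))
  src <- .resolve_source(source)
  point <- 100 * iterate_annual(src$P1, k)
  lo <- hi <- NULL
  if (!is.null(src$fit) && k >= 1) {
    bi <- bootstrap_intervals(
      src$fit,
      function(m) 100 * iterate_annual(transition_probability(
        build_Q(m), 1), k, tol = 1e-6),
      B = B, seed = seed, vcov_type = vcov_type
    )
    lo <- bi$lo; hi <- bi$hi
  } else if (!is.null(src$fit)) {
    lo <- hi <- point
  }
  structure(
    list(point = point, lo = lo, hi = hi, k = k,
         B = if (is.null(src$fit)) NA_integer_ else B,
         provenance = src$provenance),
    class = "nicomsm_projection"
  )
}

#' @export
print.nicomsm_projection <- function(x, digits = 1, ...) {
  cat(sprintf("%d-year transition probabilities (%%), source: %s\n",
              x$k, x$provenance))
  print(round(x$point, digits))
  if (!is.null(x$lo)) {
    cat(sprintf("95%% intervals from %d parametric bootstrap draws; ",
                x$B))
    cat("e.g. lower bounds:\n")
    print(round(x$lo, digits))
  }
  invisible(x)
}

#' State-occupancy projection with intervals
#'
#' The distribution over states after each of 1..K annual iterations for a
#' cohort starting in `from`, as percentages, with parametric-bootstrap
#' intervals for a fitted source.
#'
#' @inheritParams project
#' @param from Starting state label.
#' @param K Horizon in years.
#' @return data.frame with columns `year`, `state`, `pct`, `lo`, `hi`.
#' @export
occupancy_projection <- function(source, from, K, B = 1000, seed = 1,
                                 vcov_type = c("model", "sandwich")) {
  src <- .resolve_source(source)
  states <- rownames(src$P1)
  occ_fun <- function(P1) {
    as.matrix(occupancy_curve(P1, from, K)[, -1, drop = FALSE])
  }
  point <- 100 * occ_fun(src$P1)
  lo <- hi <- matrix(NA_real_, K, length(states))
  if (!is.null(src$fit)) {
    bi <- bootstrap_intervals(
      src$fit,
      function(m) 100 * occ_fun(transition_probability(build_Q(m), 1)),
      B = B, seed = seed, vcov_type = vcov_type
    )
    lo <- bi$lo; hi <- bi$hi
  }
  data.frame(
    year = rep(seq_len(K), times = length(states)),
    state = rep(states, each = K),
    pct = as.numeric(point),
    lo = as.numeric(lo),
    hi = as.numeric(hi),
    stringsAsFactors = FALSE
  )
}

#' Plot occupancy curves
#'
#' Simple base-graphics occupancy plot: one line per destination state,
#' with dashed interval bounds when present.
#'
#' @param occ data.frame from [occupancy_projection()].
#' @param main Plot title.
#' @export
plot_occupancy <- function(occ, main = "State occupancy over time") {
  states <- unique(occ$state)
  cols <- seq_along(states)
  graphics::plot(NULL, xlim = range(occ$year), ylim = c(0, 100),
                 xlab = "Years", ylab = "Occupancy (%)", main = main)
  for (i in seq_along(states)) {
    d <- occ[occ$state == states[i], ]
    graphics::lines(d$year, d$pct, col = cols[i], lwd = 2)
    if (!all(is.na(d$lo))) {
      graphics::lines(d$year, d$lo, col = cols[i], lty = 2)
      graphics::lines(d$year, d$hi, col = cols[i], lty = 2)
    }
  }
  graphics::legend("topright", legend = states, col = cols, lwd = 2,
                   bty = "n")
  invisible(NULL)
}

#' Write a projection as a provenance-annotated CSV table
#'
#' @param proj A `nicomsm_projection`.
#' @param path File path.
#' @export
write_projection_csv <- function(proj, path) {
  stopifnot(inherits(proj, "nicomsm_projection"))
  states <- rownames(proj$point)
  df <- expand.grid(from = states, to = states,
                    stringsAsFactors = FALSE)
  df$years <- proj$k
  df$pct <- proj$point[cbind(df$from, df$to)]
  df$lo <- if (is.null(proj$lo)) NA_real_ else
    proj$lo[cbind(df$from, df$to)]
  df$hi <- if (is.null(proj$hi)) NA_real_ else
    proj$hi[cbind(df$from, df$to)]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# source: ", proj$provenance,
                    "; bootstrap draws: ", proj$B), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
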