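#' Proportional-intensity model for a multistate structure
#'
#' Couples a permitted-transition structure with per-arrow baseline
#' log-intensities and, optionally, per-arrow log-hazard-ratio coefficient
#' vectors over covariate dummies. The intensity for arrow r->s under
#' covariate vector z is `q_rs(z) = exp(log_q0_rs + beta_rs' z)`, strictly
#' positive on permitted arrows and exactly zero elsewhere.
#'
#' @param struct A [transition_structure()].
#' @param log_baseline Numeric vector, one per arrow (in arrow order), of
#'   baseline log-intensities per year.
#' @param beta Optional numeric matrix, arrows x covariate terms, of
#'   log-hazard-ratios; `NULL` means a covariate-free model.
#' @param terms Character names of the covariate dummy terms (columns of
#'   `beta`).
#' @return An object of class `intensity_model`.
#' @export
intensity_model <- function(struct, log_baseline, beta = NULL,
                            terms = colnames(beta)) {
  stopifnot(inherits(struct, "transition_structure"))
  na <- nrow(struct$arrows)
  if (length(log_baseline) != na) {
    stop("need one baseline log-intensity per arrow (", na, ")")
  }
  if (!is.null(beta)) {
    beta <- as.matrix(beta)
    if (nrow(beta) != na) stop("beta must have one row per arrow")
    if (is.null(terms)) terms <- paste0("z", seq_len(ncol(beta)))
    colnames(beta) <- terms
  } else {
    beta <- matrix(0, na, 0)
    terms <- character(0)
  }
  lab <- arrow_labels(struct)
  names(log_baseline) <- lab
  rownames(beta) <- lab
  structure(
    list(struct = struct, log_baseline = log_baseline, beta = beta,
         terms = terms),
    class = "intensity_model"
  )
}

#' Arrow labels "FROM->TO" for a structure
#' @param struct A `transition_structure`.
#' @return Character vector, one label per arrow.
#' @export
arrow_labels <- function(struct) {
  paste0(struct$arrows$from, "->", struct$arrows$to)
}

#' @export
print.intensity_model <- function(x, ...) {
  cat("Proportional-intensity multistate model\n")
  cat("Baseline intensities (per year):\n")
  print(round(exp(x$log_baseline), 4))
  if (length(x$terms)) {
    cat("Hazard ratios exp(beta):\n")
    print(round(exp(x$beta), 4))
  }
  invisible(x)
}

#' Intensity matrix Q(z) generated by a model
#'
#' @param model An `intensity_model`.
#' @param z Named numeric covariate dummy vector over `model$terms`
#'   (missing or `NULL` means all-reference, i.e. baseline intensities).
#' @return Valid intensity matrix with state dimnames.
#' @export
build_Q <- function(model, z = NULL) {
  stopifnot(inherits(model, "intensity_model"))
  states <- model$struct$states
  n <- length(states)
  eta <- model$log_baseline
  if (length(model$terms)) {
    if (is.null(z)) z <- stats::setNames(numeric(length(model$terms)),
                                         model$terms)
    if (is.null(names(z))) {
      if (length(z) != length(model$terms)) {
        stop("unnamed covariate vector must match the model terms in ",
             "length and order")
      }
      names(z) <- model$terms
    }
    z <- z[model$terms]
    if (anyNA(z)) stop("covariate vector z missing terms: ",
                       paste(model$terms[is.na(z)], collapse = ", "))
    eta <- eta + drop(model$beta %*% z)
  }
  Q <- matrix(0, n, n, dimnames = list(states, states))
  Q[cbind(model$struct$arrows$from, model$struct$arrows$to)] <- exp(eta)
  diag(Q) <- -rowSums(Q)
  Q
}

# ---- interval machinery ------------------------------------------------

# Build the interval table from a coded panel: one row per consecutive
# within-subject observation pair, with the covariate dummy pattern at the
# interval's left endpoint (piecewise-constant covariates) and the
# subject-level weight (taken at the subject's first observation).
.panel_intervals <- function(panel, covariates = NULL) {
  req <- c("subject_id", "time", "state")
  miss <- setdiff(req, names(panel))
  if (length(miss)) stop("panel missing columns: ",
                         paste(miss, collapse = ", "))
  panel <- panel[order(panel$subject_id, panel$time), , drop = FALSE]
  sid <- as.character(panel$subject_id)
  same <- sid[-1] == sid[-length(sid)]
  dts <- diff(panel$time)
  if (any(same & dts <= 0)) {
    stop("observation times must be strictly increasing within subject")
  }
  idx_from <- which(same)
  idx_to <- idx_from + 1L

  w_col <- if ("weight" %in% names(panel)) panel$weight else
    rep(1, nrow(panel))
  if (any(w_col < 0, na.rm = TRUE)) stop("negative survey weights")
  first <- !duplicated(sid)
  subj_w <- stats::setNames(w_col[first], sid[first])

  if (length(covariates)) {
    miss <- setdiff(covariates, names(panel))
    if (length(miss)) stop("panel missing covariate columns: ",
                           paste(miss, collapse = ", "))
    mf <- panel[, covariates, drop = FALSE]
    mm <- stats::model.matrix(~ ., data = mf)[, -1, drop = FALSE]
  } else {
    mm <- matrix(0, nrow(panel), 0)
  }
  zpat <- if (ncol(mm)) apply(mm, 1, paste, collapse = "\r") else
    rep("", nrow(panel))
  z_from <- zpat[idx_from]
  uz <- unique(z_from)
  z_id <- match(z_from, uz)
  Z <- mm[idx_from[match(uz, z_from)], , drop = FALSE]
  rownames(Z) <- NULL

  list(
    subject = sid[idx_from],
    from = panel$state[idx_from],
    to = panel$state[idx_to],
    dt = panel$time[idx_to] - panel$time[idx_from],
    z_id = z_id,
    Z = Z,
    terms = colnames(mm),
    subject_weight = subj_w,
    n_subjects = length(subj_w),
    states = NULL
  )
}

# Rescale subject weights to mean 1 (so the weighted likelihood is on the
# effective scale of the sample size); returns per-interval weights.
.interval_weights <- function(iv, rescale = TRUE) {
  w <- iv$subject_weight
  if (all(w == 0)) stop("all survey weights are zero")
  if (rescale) w <- w / mean(w)
  unname(w[iv$subject])
}

# Aggregate intervals into groups sharing (z pattern, dt, from, to); the
# log-likelihood is then a weighted sum of log P(dt)[from,to] over groups.
.group_intervals <- function(iv, states, w) {
  fi <- match(iv$from, states)
  ti <- match(iv$to, states)
  if (anyNA(fi) || anyNA(ti)) {
    bad <- unique(c(iv$from[is.na(fi)], iv$to[is.na(ti)]))
    stop("panel states not in structure: ", paste(bad, collapse = ", "))
  }
  key <- paste(iv$z_id, iv$dt, fi, ti, sep = "\r")
  uk <- !duplicated(key)
  g <- list(
    z_id = iv$z_id[uk],
    dt = iv$dt[uk],
    from = fi[uk],
    to = ti[uk],
    w = as.numeric(rowsum(w, key, reorder = FALSE))
  )
  # rowsum orders by first appearance with reorder = FALSE
  g
}

# Grouped weighted log-likelihood for packed parameters. Entries that
# underflow to zero contribute log(.Machine$double.xmin) so optimisers see
# a finite, steeply penalised surface; structural zeros are excluded
# before fitting via the reachability check.
.loglik_grouped <- function(par, skel, g) {
  model <- .unpack(par, skel)
  ll <- 0
  for (zi in seq_len(max(g$z_id))) {
    sel <- g$z_id == zi
    if (!any(sel)) next
    z <- if (length(skel$terms)) skel$Z[zi, ] else NULL
    Q <- build_Q(model, z)
    ent <- .tpm_entries(Q, g$dt[sel], g$from[sel], g$to[sel])
    ent[ent < 1e-300] <- 1e-300
    ll <- ll + sum(g$w[sel] * log(ent))
  }
  ll
}

# per-interval log-likelihood vector (unweighted), same machinery
.loglik_intervals <- function(par, skel, iv, states) {
  model <- .unpack(par, skel)
  fi <- match(iv$from, states); ti <- match(iv$to, states)
  out <- numeric(length(iv$dt))
  for (zi in seq_len(nrow(skel$Z) + as.integer(nrow(skel$Z) == 0))) {
    sel <- iv$z_id == zi
    if (!any(sel)) next
    z <- if (length(skel$terms)) skel$Z[zi, ] else NULL
    Q <- build_Q(model, z)
    ent <- .tpm_entries(Q, iv$dt[sel], fi[sel], ti[sel])
    ent[ent < 1e-300] <- 1e-300
    out[sel] <- log(ent)
  }
  out
}

.pack <- function(model) {
  c(model$log_baseline, as.vector(model$beta))
}

.unpack <- function(par, skel) {
  na <- nrow(skel$struct$arrows)
  nt <- length(skel$terms)
  lb <- par[seq_len(na)]
  beta <- if (nt) matrix(par[na + seq_len(na * nt)], na, nt) else NULL
  intensity_model(skel$struct, lb, beta, terms = skel$terms)
}

.par_names <- function(struct, terms) {
  lab <- arrow_labels(struct)
  c(paste0("logq(", lab, ")"),
    if (length(terms)) as.vector(outer(lab, terms, function(a, t)
      paste0("beta(", a, ").", t))))
}

.numgrad <- function(f, par, h = 1e-6) {
  sapply(seq_along(par), function(j) {
    hj <- h * max(1, abs(par[j]))
    up <- par; up[j] <- up[j] + hj
    dn <- par; dn[j] <- dn[j] - hj
    (f(up) - f(dn)) / (2 * hj)
  })
}

# ---- exported likelihood operations ------------------------------------

#' Log-likelihood of one interval-censored observation pair
#'
#' The panel likelihood conditions only on the state at the earlier of two
#' consecutive interviews: the contribution is the log of entry
#' `[from, to]` of P(dt) = exp(dt Q(z)), with the covariate vector z taken
#' at the earlier interview (piecewise-constant covariates). A pair that is
#' impossible under the permitted structure (for example any re-entry into
#' never use) has probability zero and returns `-Inf` with a warning
#' identifying the pair, which usually signals structure misspecification.
#'
#' @param model An `intensity_model`.
#' @param from,to State labels at the earlier and later interview.
#' @param dt Positive elapsed time in years.
#' @param z Named covariate dummy vector at the earlier interview.
#' @return Scalar log-probability.
#' @export
interval_log_likelihood <- function(model, from, to, dt, z = NULL) {
  stopifnot(dt > 0)
  reach <- reachability_matrix(model$struct)
  if (!reach[from, to]) {
    warning("observed pair ", from, "->", to, " over ", dt,
            " years has probability 0 under the permitted structure",
            call. = FALSE)
    return(-Inf)
  }
  Q <- build_Q(model, z)
  P <- transition_probability(Q, dt)
  p <- P[from, to]
  if (p <= 0) return(-Inf)
  log(p)
}

#' Survey-weighted panel log-likelihood
#'
#' Sum over subjects of the subject's survey weight times the sum of
#' interval log-likelihoods over the subject's consecutive observation
#' pairs. Weights are taken at each subject's first observation and, by
#' default, rescaled to mean 1 across subjects so that the weighted
#' likelihood is on the scale of the sample size (and point estimates are
#' invariant to the overall weight scale).
#'
#' @param model An `intensity_model`.
#' @param panel Coded panel data.frame (`subject_id`, `time`, `state`,
#'   covariate columns, optional `weight`).
#' @param covariates Character vector of covariate column names (must
#'   generate exactly the model's terms).
#' @param rescale_weights Rescale subject weights to mean 1 (default TRUE).
#' @return Scalar weighted log-likelihood (may be `-Inf`, with a warning,
#'   when the panel contains structurally impossible pairs).
#' @export
weighted_log_likelihood <- function(model, panel, covariates = NULL,
                                    rescale_weights = TRUE) {
  iv <- .panel_intervals(panel, covariates)
  if (length(iv$terms) != length(model$terms) ||
      !all(iv$terms == model$terms)) {
    stop("covariate terms from panel (", paste(iv$terms, collapse = ", "),
         ") do not match model terms (",
         paste(model$terms, collapse = ", "), ")")
  }
  states <- model$struct$states
  reach <- reachability_matrix(model$struct)
  bad <- !reach[cbind(match(iv$from, states), match(iv$to, states))]
  if (any(bad)) {
    pairs <- unique(paste0(iv$from[bad], "->", iv$to[bad]))
    warning("panel contains structurally impossible pairs: ",
            paste(pairs, collapse = ", "), call. = FALSE)
    return(-Inf)
  }
  w <- .interval_weights(iv, rescale_weights)
  skel <- list(struct = model$struct, terms = model$terms, Z = iv$Z)
  g <- .group_intervals(iv, states, w)
  .loglik_grouped(.pack(model), skel, g)
}

#' Crude initial transition rates
#'
#' Occurrence/exposure starting values for the optimiser: for each
#' permitted arrow r->s, the weighted count of observed r-to-s interval
#' patterns divided by the weighted person-time observed starting in r,
#' floored at a small positive rate so that arrows without observed
#' patterns still start strictly positive.
#'
#' @param panel Coded panel data.frame.
#' @param struct A `transition_structure`.
#' @param floor Minimum rate per year (default 1e-4).
#' @param rescale_weights Rescale subject weights to mean 1.
#' @return A covariate-free `intensity_model` with the crude rates.
#' @export
crude_initial_rates <- function(panel, struct = transition_structure(),
                                floor = 1e-4, rescale_weights = TRUE) {
  iv <- .panel_intervals(panel, NULL)
  w <- .interval_weights(iv, rescale_weights)
  na <- nrow(struct$arrows)
  rates <- numeric(na)
  for (a in seq_len(na)) {
    r <- struct$arrows$from[a]; s <- struct$arrows$to[a]
    n_rs <- sum(w[iv$from == r & iv$to == s])
    pt_r <- sum(w[iv$from == r] * iv$dt[iv$from == r])
    rates[a] <- if (pt_r > 0) n_rs / pt_r else 0
  }
  rates <- pmax(rates, floor)
  intensity_model(struct, log(rates))
}

#' Fit a weighted continuous-time multistate Markov model
#'
#' Maximises the survey-weighted interval-censored panel likelihood over
#' per-arrow baseline log-intensities and (optionally) per-arrow
#' log-hazard-ratio coefficients for categorical covariates, by BFGS
#' quasi-Newton iteration from crude occurrence/exposure starting values.
#' Covariates act proportionally on the intensities and are held
#' piecewise-constant at their value at the start of each observation
#' interval. Two covariance estimates are reported: the inverse observed
#' information of the weighted log-likelihood ("model"), and a
#' design-based sandwich estimate built from per-subject score
#' contributions ("sandwich"), which is the safer choice when weights
#' vary.
#'
#' @param panel Coded panel data.frame: `subject_id`, `time`, `state`,
#'   optional `weight`, plus any covariate factor columns.
#' @param struct A `transition_structure`.
#' @param covariates Character vector of covariate column names, or `NULL`
#'   for the unadjusted model. Every covariate affects every arrow.
#' @param rescale_weights Rescale subject weights to mean 1 (default TRUE).
#' @param control List: `maxit` (500), `factr` (1e7, relative
#'   log-likelihood convergence factor of the bounded quasi-Newton
#'   search), `grad_tol` (1e-5, gradient-norm threshold reported in
#'   diagnostics), `init_floor` (1e-4), `boundary_rate` (1e-5, below
#'   which a fitted intensity is flagged as at the zero boundary),
#'   `logq_bounds` / `beta_bounds` (search boxes on the log scale).
#' @return Object of class `nicomsm_fit` with components `model` (the
#'   fitted `intensity_model`), `estimates`, `vcov_model`,
#'   `vcov_sandwich`, `loglik`, `convergence`, `gradient_norm`,
#'   `n_subjects`, `n_intervals`, and bookkeeping fields.
#' @export
fit_msm <- function(panel, struct = transition_structure(),
                    covariates = NULL, rescale_weights = TRUE,
                    control = list()) {
  ctl <- utils::modifyList(
    list(maxit = 500, factr = 1e7, grad_tol = 1e-5,
         init_floor = 1e-4, boundary_rate = 1e-5,
         logq_bounds = c(-20, 10), beta_bounds = c(-10, 10)),
    control
  )
  iv <- .panel_intervals(panel, covariates)
  states <- struct$states
  reach <- reachability_matrix(struct)
  fi <- match(iv$from, states); ti <- match(iv$to, states)
  if (anyNA(fi) || anyNA(ti)) {
    stop("panel states not in structure: ",
         paste(unique(c(iv$from[is.na(fi)], iv$to[is.na(ti)])),
               collapse = ", "))
  }
  bad <- !reach[cbind(fi, ti)]
  if (any(bad)) {
    stop("non-finite likelihood at initial values: observed pairs ",
         paste(unique(paste0(iv$from[bad], "->", iv$to[bad])),
               collapse = ", "),
         " are impossible under the permitted structure; ",
         "check the structure against the data")
  }
  # warn when an arrow has no corresponding observed interval pattern
  seen <- unique(paste0(iv$from, "->", iv$to))
  unseen <- setdiff(arrow_labels(struct), seen)
  if (length(unseen)) {
    warning("no observed interval pattern for arrow(s): ",
            paste(unseen, collapse = ", "),
            "; the corresponding intensities may drift to the zero ",
            "boundary", call. = FALSE)
  }

  w <- .interval_weights(iv, rescale_weights)
  g <- .group_intervals(iv, states, w)
  init <- crude_initial_rates(panel, struct, floor = ctl$init_floor,
                              rescale_weights = rescale_weights)
  skel <- list(struct = struct, terms = iv$terms, Z = iv$Z)
  na <- nrow(struct$arrows); nt <- length(iv$terms)
  par0 <- c(init$log_baseline, rep(0, na * nt))
  pn <- .par_names(struct, iv$terms)
  names(par0) <- pn

  negll <- function(par) -.loglik_grouped(par, skel, g)
  gr <- function(par) .numgrad(negll, par)

  # box constraints keep the quasi-Newton search inside the region where
  # the matrix exponential is numerically trustworthy; the bounds are far
  # outside any epidemiologically plausible intensity
  lower <- c(rep(ctl$logq_bounds[1], na), rep(ctl$beta_bounds[1],
                                              na * nt))
  upper <- c(rep(ctl$logq_bounds[2], na), rep(ctl$beta_bounds[2],
                                              na * nt))
  opt <- stats::optim(par0, negll, gr = gr, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = ctl$maxit,
                                     factr = ctl$factr))
  grad <- gr(opt$par)
  gnorm <- sqrt(sum(grad^2))
  if (opt$convergence != 0) {
    stop("optimisation did not converge within ", ctl$maxit,
         " iterations (optim code ", opt$convergence,
         ", gradient norm ", signif(gnorm, 4), ")")
  }
  est <- stats::setNames(opt$par, pn)
  model <- .unpack(est, skel)

  low_rate <- exp(model$log_baseline) < ctl$boundary_rate
  if (any(low_rate)) {
    warning("fitted intensity at the zero boundary for arrow(s): ",
            paste(names(model$log_baseline)[low_rate], collapse = ", "),
            call. = FALSE)
  }

  H <- tryCatch(stats::optimHess(est, negll), error = function(e) NULL)
  vcov_model <- NULL
  if (!is.null(H)) {
    vcov_model <- tryCatch(solve(H), error = function(e) NULL)
  }
  if (is.null(vcov_model)) {
    warning("observed information is singular; covariance unavailable ",
            "(model near a boundary?)", call. = FALSE)
    vcov_model <- matrix(NA_real_, length(est), length(est))
  }
  dimnames(vcov_model) <- list(pn, pn)

  # design-based sandwich from per-subject scores (finite differences of
  # the per-subject weighted log-likelihood)
  vcov_sandwich <- matrix(NA_real_, length(est), length(est),
                          dimnames = list(pn, pn))
  if (all(is.finite(vcov_model))) {
    subj_ll <- function(par) {
      li <- .loglik_intervals(par, skel, iv, states)
      as.numeric(rowsum(li, iv$subject, reorder = FALSE)) *
        w[!duplicated(iv$subject)]
    }
    S <- sapply(seq_along(est), function(j) {
      hj <- 1e-6 * max(1, abs(est[j]))
      up <- est; up[j] <- up[j] + hj
      dn <- est; dn[j] <- dn[j] - hj
      (subj_ll(up) - subj_ll(dn)) / (2 * hj)
    })
    B <- crossprod(S)
    vcov_sandwich <- vcov_model %*% B %*% vcov_model
    dimnames(vcov_sandwich) <- list(pn, pn)
  }

  res <- structure(
    list(model = model, estimates = est, vcov_model = vcov_model,
         vcov_sandwich = vcov_sandwich, loglik = -opt$value,
         convergence = TRUE, optim_counts = opt$counts,
         gradient_norm = gnorm, grad_tol = ctl$grad_tol,
         n_subjects = iv$n_subjects, n_intervals = length(iv$dt),
         struct = struct, covariates = covariates, terms = iv$terms,
         weights_varied = stats::sd(iv$subject_weight) > 0,
         call = match.call()),
    class = "nicomsm_fit"
  )
  res
}

#' @export
print.nicomsm_fit <- function(x, ...) {
  cat("Weighted continuous-time multistate Markov model fit\n")
  cat(sprintf("  %d subjects, %d observation intervals, loglik %.3f\n",
              x$n_subjects, x$n_intervals, x$loglik))
  cat(sprintf("  converged (gradient norm %.2e)\n", x$gradient_norm))
  cat("Baseline intensities (per year):\n")
  print(round(exp(x$model$log_baseline), 4))
  if (length(x$terms)) {
    cat("Hazard ratios: see hazard_ratios()\n")
  }
  invisible(x)
}

#' @export
coef.nicomsm_fit <- function(object, ...) object$estimates

#' @export
vcov.nicomsm_fit <- function(object, type = c("model", "sandwich"), ...) {
  type <- match.arg(type)
  if (type == "model") object$vcov_model else object$vcov_sandwich
}

#' @export
logLik.nicomsm_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$estimates),
            class = "logLik")
}

#' Hazard-ratio table from a fitted model
#'
#' Exponentiates each per-arrow covariate coefficient into a hazard ratio
#' relative to the reference category (age 14-17, female, white, low
#' income), with Wald confidence intervals `exp(beta +/- z * SE)`.
#'
#' @param fit A converged `nicomsm_fit` with covariates.
#' @param conf Confidence level (default 0.95).
#' @param vcov_type `"model"` or `"sandwich"` standard errors.
#' @return data.frame: `from`, `to`, `term`, `HR`, `lo`, `hi`, `log_hr`,
#'   `se`.
#' @export
hazard_ratios <- function(fit, conf = 0.95,
                          vcov_type = c("model", "sandwich")) {
  stopifnot(inherits(fit, "nicomsm_fit"))
  vcov_type <- match.arg(vcov_type)
  if (!length(fit$terms)) stop("fit has no covariates")
  V <- vcov(fit, vcov_type)
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  lab <- arrow_labels(fit$struct)
  rows <- expand.grid(arrow = lab, term = fit$terms,
                      stringsAsFactors = FALSE)
  pn <- paste0("beta(", rows$arrow, ").", rows$term)
  b <- fit$estimates[pn]
  se <- sqrt(diag(V)[pn])
  ft <- do.call(rbind, strsplit(rows$arrow, "->", fixed = TRUE))
  data.frame(
    from = ft[, 1], to = ft[, 2], term = rows$term,
    HR = exp(b), lo = exp(b - zq * se), hi = exp(b + zq * se),
    log_hr = b, se = se,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Write / read a fit artifact as JSON
#'
#' Serialises the estimates, both covariance matrices and the convergence
#' diagnostics (not the data) so that downstream projection can be run
#' from a stored fit.
#'
#' @param fit A `nicomsm_fit`.
#' @param path File path.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "nicomsm_fit"))
  obj <- list(
    estimates = as.list(fit$estimates),
    vcov_model = fit$vcov_model,
    vcov_sandwich = fit$vcov_sandwich,
    loglik = fit$loglik,
    gradient_norm = fit$gradient_norm,
    n_subjects = fit$n_subjects,
    n_intervals = fit$n_intervals,
    states = fit$struct$states,
    arrows = fit$struct$arrows,
    terms = fit$terms
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
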