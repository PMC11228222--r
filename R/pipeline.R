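#' Baseline descriptive table
#'
#' Counts and column percentages of baseline characteristics (first
#' observation per subject) stratified by baseline nicotine-product-use
#' state, with a Pearson chi-square p-value per characteristic. Counts are
#' unweighted, as is conventional for survey descriptive tables.
#'
#' @param panel Coded panel data.frame.
#' @param characteristics Covariate columns to tabulate; the number of
#'   observed waves per subject is always included.
#' @return data.frame: `characteristic`, `level`, one count column per
#'   state, `total`, `p_value` (repeated within characteristic).
#' @export
descriptive_table <- function(panel,
                              characteristics = c("age_band", "sex",
                                                  "ethnicity",
                                                  "income_tertile")) {
  panel <- panel[order(panel$subject_id, panel$time), , drop = FALSE]
  first <- !duplicated(panel$subject_id)
  base <- panel[first, , drop = FALSE]
  base$n_waves <- as.integer(table(panel$subject_id)[base$subject_id])
  states <- intersect(nicotine_states(), unique(base$state))
  chars <- c("n_waves", intersect(characteristics, names(base)))
  out <- NULL
  for (ch in chars) {
    tab <- table(factor(base[[ch]]), factor(base$state, levels = states))
    p <- tryCatch(
      suppressWarnings(stats::chisq.test(tab)$p.value),
      error = function(e) NA_real_
    )
    df <- data.frame(characteristic = ch, level = rownames(tab),
                     stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame.matrix(tab))
    df$total <- rowSums(tab)
    df$p_value <- p
    out <- rbind(out, df)
  }
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' Reproduces the standard analysis flow on a coded panel (or a freshly
#' simulated one): baseline descriptive table, unadjusted fit, one-year
#' transition-probability table, covariate-adjusted fit with hazard-ratio
#' table, and one-to-five-year projections with parametric-bootstrap
#' intervals. Projection uses the unadjusted model. When `out_dir` is
#' given, all tables are written as CSV, fits as JSON, and a structured
#' text log records the seed, package version, record counts and the
#' configuration snapshot.
#'
#' @param panel Coded panel data.frame, or `NULL` to simulate from
#'   `config`.
#' @param config A [sim_config()] used when `panel` is `NULL` (and
#'   recorded in the log regardless).
#' @param covariates Covariates for the adjusted fit.
#' @param struct A `transition_structure`.
#' @param horizon Projection horizon in years.
#' @param B Parametric bootstrap draws for interval estimation.
#' @param seed Seed for the bootstrap.
#' @param out_dir Optional output directory.
#' @return Invisibly, a bundle list: `panel`, `descriptive`,
#'   `fit_unadjusted`, `fit_adjusted`, `one_year`, `hazard_ratios`,
#'   `projections` (list by horizon), `occupancy`, `seed`.
#' @export
run_main <- function(panel = NULL, config = sim_config(),
                     covariates = c("age_band", "sex", "ethnicity",
                                    "income_tertile"),
                     struct = transition_structure(), horizon = 5,
                     B = 500, seed = 1, out_dir = NULL) {
  if (is.null(panel)) {
    sim <- simulate_panel(config)
    panel <- sim$panel
  }
  desc <- descriptive_table(panel)
  fit_u <- fit_msm(panel, struct)
  one_yr <- one_year_table(fit_u, B = B, seed = seed)
  fit_a <- fit_msm(panel, struct, covariates = covariates)
  hrs <- hazard_ratios(fit_a)
  projections <- lapply(seq_len(horizon), function(k)
    project(fit_u, k, B = B, seed = seed))
  names(projections) <- paste0("year", seq_len(horizon))
  occ <- do.call(rbind, lapply(struct$states, function(s) {
    do.call(rbind, lapply(seq_len(horizon), function(k) {
      pr <- projections[[k]]
      data.frame(from = s, year = k, state = struct$states,
                 pct = pr$point[s, ], lo = pr$lo[s, ], hi = pr$hi[s, ],
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
  }))
  bundle <- list(panel = panel, descriptive = desc, fit_unadjusted = fit_u,
                 fit_adjusted = fit_a, one_year = one_yr,
                 hazard_ratios = hrs, projections = projections,
                 occupancy = occ, seed = seed)
  if (!is.null(out_dir)) {
    .write_bundle(bundle, config, out_dir)
  }
  invisible(bundle)
}

.write_bundle <- function(bundle, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(out_dir, f)
  utils::write.csv(bundle$descriptive, fp("descriptive_table.csv"),
                   row.names = FALSE)
  write_projection_csv(bundle$one_year, fp("one_year_table.csv"))
  utils::write.csv(bundle$hazard_ratios, fp("hazard_ratios.csv"),
                   row.names = FALSE)
  for (nm in names(bundle$projections)) {
    write_projection_csv(bundle$projections[[nm]],
                         fp(paste0("projection_", nm, ".csv")))
  }
  utils::write.csv(bundle$occupancy, fp("occupancy.csv"),
                   row.names = FALSE)
  write_fit_json(bundle$fit_unadjusted, fp("fit_unadjusted.json"))
  write_fit_json(bundle$fit_adjusted, fp("fit_adjusted.json"))
  cfg <- config
  cfg$truth <- NULL
  log_lines <- c(
    paste0("run at: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0("package version: ",
           as.character(utils::packageVersion("nicomsm"))),
    paste0("seed: ", bundle$seed),
    paste0("subjects: ", bundle$fit_unadjusted$n_subjects),
    paste0("observation intervals: ",
           bundle$fit_unadjusted$n_intervals),
    paste0("config: ",
           jsonlite::toJSON(cfg[!vapply(cfg, is.function, TRUE)],
                            auto_unbox = TRUE, null = "null"))
  )
  writeLines(log_lines, fp("run_log.txt"))
  invisible(out_dir)
}

# CI-overlap comparison of per-arrow log-intensities between two fits
.compare_fits <- function(fit_main, fit_sub, conf = 0.95,
                          vcov_type = "model") {
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  lab <- arrow_labels(fit_main$struct)
  pn <- paste0("logq(", lab, ")")
  ci <- function(fit) {
    b <- fit$estimates[pn]
    se <- sqrt(diag(vcov(fit, vcov_type))[pn])
    cbind(est = b, lo = b - zq * se, hi = b + zq * se)
  }
  m <- ci(fit_main); s <- ci(fit_sub)
  data.frame(
    arrow = lab,
    est_main = m[, "est"], lo_main = m[, "lo"], hi_main = m[, "hi"],
    est_subset = s[, "est"], lo_subset = s[, "lo"],
    hi_subset = s[, "hi"],
    ci_overlap = !(m[, "hi"] < s[, "lo"] | s[, "hi"] < m[, "lo"]),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Sensitivity analyses
#'
#' Refits the model on a defined subset of the panel and compares the
#' per-arrow log-intensity estimates with the main fit, flagging arrows
#' whose 95% confidence intervals do not overlap (overlapping intervals
#' across all arrows is the robustness criterion). Available analyses:
#'
#' * `drop_wave7`: exclude the first (binary e-cigarette question) wave;
#' * `drop_covid`: exclude interviews whose `interview_date` falls in the
#'   UK COVID-19 restriction window (2020-03-01 to 2021-07-31 inclusive);
#' * `drop_assumed_noncurrent`: exclude subjects whose baseline state was
#'   assumed non-current (the age-16-plus classification rule);
#' * `homogeneity`: fit each consecutive two-wave subsample and compare
#'   with the pooled estimates (a check of time-homogeneity).
#'
#' @param panel Coded panel data.frame.
#' @param which One of `"drop_wave7"`, `"drop_covid"`,
#'   `"drop_assumed_noncurrent"`, `"homogeneity"`.
#' @param struct A `transition_structure`.
#' @param conf Confidence level for the overlap comparison.
#' @param covid_window Dates delimiting the exclusion window.
#' @return List: `which`, `comparison` (data.frame; for `homogeneity` one
#'   block per wave pair with a `wave_pair` column), `n_subjects_main`,
#'   `n_subjects_subset`, `n_records_main`, `n_records_subset`.
#' @export
run_sensitivity <- function(panel,
                            which = c("drop_wave7", "drop_covid",
                                      "drop_assumed_noncurrent",
                                      "homogeneity"),
                            struct = transition_structure(), conf = 0.95,
                            covid_window = as.Date(c("2020-03-01",
                                                     "2021-07-31"))) {
  which <- match.arg(which)
  fit_main <- fit_msm(panel, struct)

  if (which == "homogeneity") {
    waves <- sort(unique(panel$wave))
    comp <- NULL
    for (i in seq_len(length(waves) - 1)) {
      sub <- drop_singletons(
        panel[panel$wave %in% waves[c(i, i + 1)], , drop = FALSE])
      if (!nrow(sub)) next
      fit_s <- tryCatch(
        suppressWarnings(fit_msm(sub, struct)),
        error = function(e) NULL
      )
      if (is.null(fit_s)) next
      ci <- .compare_fits(fit_main, fit_s, conf)
      ci$wave_pair <- paste0(waves[i], "-", waves[i + 1])
      comp <- rbind(comp, ci)
    }
    if (is.null(comp)) stop("no two-wave subsample is fittable")
    return(list(which = which, comparison = comp,
                n_subjects_main = fit_main$n_subjects,
                n_records_main = nrow(panel)))
  }

  sub <- switch(
    which,
    drop_wave7 = panel[panel$wave != min(panel$wave), , drop = FALSE],
    drop_covid = {
      if (!"interview_date" %in% names(panel)) {
        stop("drop_covid needs an interview_date column")
      }
      d <- as.Date(panel$interview_date)
      panel[d < covid_window[1] | d > covid_window[2], , drop = FALSE]
    },
    drop_assumed_noncurrent = {
      flagged <- unique(panel$subject_id[panel$assumed_noncurrent])
      panel[!panel$subject_id %in% flagged, , drop = FALSE]
    }
  )
  sub <- drop_singletons(sub)
  if (!nrow(sub)) {
    stop("sensitivity subset '", which,
         "' leaves no subject with two or more observations")
  }
  fit_sub <- suppressWarnings(fit_msm(sub, struct))
  list(which = which,
       comparison = .compare_fits(fit_main, fit_sub, conf),
       n_subjects_main = fit_main$n_subjects,
       n_subjects_subset = fit_sub$n_subjects,
       n_records_main = nrow(panel),
       n_records_subset = nrow(sub))
}

#' Verify multi-year projections of the published one-year matrix
#'
#' Row-normalises the bundled published one-year transition matrix,
#' iterates it over the published horizons, rounds to whole percent (the
#' multi-year reporting convention) and compares with the published
#' multi-year percentages.
#'
#' @return data.frame: `from`, `to`, `years`, `computed_pct` (whole
#'   percent), `published_pct`, `pass`.
#' @export
#' @examples
#' verify_printed_projections()
verify_printed_projections <- function() {
  P1 <- normalise_printed(reference_one_year_matrix())
  ref <- utils::read.csv(
    system.file("extdata", "uk_youth_multiyear_pct.csv",
                package = "nicomsm"),
    stringsAsFactors = FALSE
  )
  ref$computed_pct <- NA_real_
  for (i in seq_len(nrow(ref))) {
    Pk <- iterate_annual(P1, ref$years[i])
    ref$computed_pct[i] <- round(100 * Pk[ref$from[i], ref$to[i]])
  }
  ref$pass <- ref$computed_pct == ref$published_pct
  ref[, c("from", "to", "years", "computed_pct", "published_pct",
          "pass")]
}

#' Read a run configuration file (YAML or JSON)
#'
#' Reads a configuration file whose top-level keys are [sim_config()]
#' arguments (unknown keys are ignored; `truth` may not be configured
#' from file and defaults to [default_truth_model()]).
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return A `sim_config`.
#' @export
read_run_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be .yaml, .yml or .json")
  }
  args <- obj[intersect(names(obj), names(formals(sim_config)))]
  args$truth <- NULL
  if (!is.null(args$study_start)) {
    args$study_start <- as.Date(args$study_start)
  }
  if (!is.null(args$income_probs)) {
    args$income_probs <- unlist(args$income_probs)
  }
  if (!is.null(args$age_band_probs)) {
    args$age_band_probs <- unlist(args$age_band_probs)
  }
  do.call(sim_config, args)
}
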