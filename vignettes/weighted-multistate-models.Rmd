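---
title: "Weighted continuous-time multistate models for youth nicotine product transitions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted continuous-time multistate models for youth nicotine product transitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nicomsm)
```

## The model

`nicomsm` models movement among four nicotine-product-use states —
never use (`NEVER`), non-current use (`NONCURRENT`), current
e-cigarette-only use (`ECIG_ONLY`) and current cigarette smoking
including dual use (`SMOKING`) — as a continuous-time Markov chain. The
chain is characterised by an intensity matrix $Q$ whose off-diagonal
entry $q_{rs}$ is the instantaneous rate (per year) of moving from state
$r$ to state $s$, and whose diagonal is minus the row sum. Transition
probabilities over a horizon $t$ follow from the matrix exponential,
$P(t) = e^{tQ}$, and multi-year projections iterate the one-year matrix,
$P(k) = P(1)^k$.

Not every instantaneous movement is possible. The default permitted
structure has eight arrows: never users can start either product
directly; non-current and current users move among themselves in any
direction; and nothing re-enters `NEVER`, because never use is
unrecoverable by definition. The direct `ECIG_ONLY` ↔ `SMOKING` arrows
are included — the data show substantial year-on-year movement between
the two current-use states — but the arrow set is an explicit,
JSON-serialisable object (`transition_structure()`), so any alternative
topology can be supplied and audited.

Covariates act proportionally on the intensities:
$q_{rs}(z) = q^{(0)}_{rs} \exp(\beta_{rs}^\top z)$, so each
$\exp(\beta)$ is a transition-specific hazard ratio. Every arrow gets
its own coefficient vector; nothing is shared across arrows. Reference
categories are age 14–17, female, white and low income, so hazard
ratios read as contrasts against the group with the highest product
uptake. Time-varying covariates (age band) are handled
piecewise-constantly: the covariate value at the start of each
observation interval governs the whole interval.

## The interval-censored likelihood

Survey panels observe subjects only at interviews, roughly a year
apart; what happened between interviews is unobserved. The likelihood
therefore conditions each observation on the previous one only: for a
subject observed in state $r$ at time $t_1$ and state $s$ at time
$t_2$, the contribution is $\log P(t_2 - t_1)[r, s]$ with $Q$ evaluated
at the covariates in force at $t_1$. Subjects contribute the product of
their consecutive-pair terms; subjects seen only once contribute
nothing and are excluded. A pair that is impossible under the permitted
structure (any re-entry to `NEVER`) has probability exactly zero; the
likelihood reports it by name because it almost always means the
structure, not the data, is wrong.

Survey weights enter as frequency-style multipliers of each subject's
log-likelihood contribution. Weights are taken at the subject's first
observation and rescaled to mean one across subjects, which makes point
estimates invariant to the overall weight scale and keeps the weighted
log-likelihood on the scale of the sample size. Because the weighted
score is not a true likelihood score, `fit_msm()` reports two
covariance estimates: the inverse observed information of the weighted
log-likelihood ("model"), and a design-based sandwich built from
per-subject score contributions ("sandwich"). With variable weights the
sandwich is the defensible default and is what the package's own
simulation checks use; with equal weights the two coincide
asymptotically. Both are reported rather than choosing silently,
because weighted multistate practice is not settled on one.

## Numerical choices

* **Matrix exponential.** `transition_probability()` uses the dense
  scaling-and-squaring algorithm in `Matrix::expm()`. Inside the
  likelihood, where $P(\Delta t)$ entries are needed for thousands of
  distinct interval lengths, an eigendecomposition fast path evaluates
  all entries for one $Q$ in a single vectorised pass; it is used only
  when $V \Lambda V^{-1}$ reconstructs $Q$ to $10^{-9}$ relative
  accuracy, and otherwise falls back to one `expm` per unique interval
  length. The test suite holds both routes to a 60-term truncated-series
  oracle at $10^{-8}$.
* **Optimisation.** Intensities are log-parameterised (hence
  unconstrained in sign) and maximised by bounded quasi-Newton
  (`L-BFGS-B`) from crude occurrence/exposure starting rates floored at
  $10^{-4}$/year, with numerical central-difference gradients,
  convergence factor $10^7 \varepsilon$ on the log-likelihood, and at
  most 500 iterations. The box $\log q \in [-20, 10]$ keeps the search
  inside the region where the matrix exponential is numerically
  trustworthy — an overflowing $e^{tQ}$ can silently return a
  non-stochastic matrix, which the likelihood additionally detects and
  treats as an invalid region. A fitted rate below $10^{-5}$/year is
  flagged as a zero-boundary solution.
* **Row-stochasticity.** Published transition tables are rounded, so
  rows can sum to slightly off 100% (the non-current row of the
  packaged reference matrix sums to 100.1). `normalise_printed()`
  divides each row by its sum and keeps the raw input as provenance;
  downstream checks enforce row sums of one to $10^{-8}$.
* **Intervals.** Uncertainty for projections and derived quantities
  uses a seeded parametric bootstrap: draw parameter vectors from the
  fit's asymptotic normal, recompute the functional, take 2.5/97.5
  percentiles. The default is $B = 1000$ draws; the construction of
  published interval estimates for such projections is typically
  unstated, and the delta method is the obvious alternative — the
  bootstrap was chosen because it respects range restrictions near 0
  and 1.

## Questionnaire coding

The coding rules translate two questionnaire eras into one state
variable. The first study wave asked a binary "do you ever use
e-cigarettes" question; later waves used six categories, of which
everything except *never* and *in the past but not now* counts as
current use. Smoking is a binary current-use question throughout for
16–25 year-olds, while 10–15 year-olds are asked about ever use.

That age split has one important consequence: a non-using respondent
first seen at age 16 or over cannot demonstrate never-use, so they are
classified non-current with an `assumed_noncurrent` flag, and the
assumption propagates — their later non-use waves stay non-current
rather than reverting to never. The flag drives a dedicated sensitivity
analysis (`run_sensitivity(..., "drop_assumed_noncurrent")`). A second,
smaller information loss is irreducible at binary waves: prior use by a
respondent under 16 cannot be expressed there, and the round-trip tests
document exactly these two divergences and no others.

Household income is equivalised before tertile assignment. The package
defaults to the modified OECD scale (1.0 / 0.5 per additional adult /
0.3 per child under 14), the convention of UK household panel income
variables, with the original OECD scale (1.0 / 0.7 / 0.5) selectable
because published analyses often do not say which was used. Tertile
cutoffs are £1191 and £1787 of equivalised monthly income, with both
boundary values belonging to the middle band (matching the printed
interval notation, which is closed at the mid endpoints).

## The synthetic generator

`simulate_panel()` emulates the structure of an annual UK youth
household panel so that every stage of the pipeline is testable without
licensed microdata. Its defaults are the study-like conditions used
throughout the package's validation:

* 10 000 subjects over six annual waves, interview dates jittered with
  SD 0.08 years (no published jitter magnitude exists; this is a
  declared convention of roughly a month);
* entry ages 10–25 with band probabilities 36/26/22/16%, baseline
  state drawn conditional on age band (never use dominating at 10–13
  and falling steeply with age);
* covariate marginals 47% male, 71% white, income tertiles 39/34/28%;
* survey weights lognormal with mean 1 (SD of log 0.3);
* attrition missing-completely-at-random at 0.15 per wave — chosen to
  give a realistic spread of follow-up lengths; real panels also have
  staggered entry, which the generator does not model — plus ageing
  out of the 10–25 range;
* ground-truth intensities `default_truth_Q()`: the matrix logarithm
  of the row-normalised published one-year matrix projected onto the
  permitted arrow set. The projection zeroes one tiny negative entry
  and the small direct never-to-non-current cell, so the truth is an
  approximation that reproduces the published matrix to about
  $4 \times 10^{-4}$ — close enough that synthetic panels resemble the
  study, but not a published estimate.

Sampling the chain only at interview times is exact — the skeleton of a
CTMC is a Markov chain with transition matrices $P(\Delta t)$ — and is
how large panels are generated. The event-level path sampler
(`simulate_trajectory()`), which draws exponential sojourns and
destinations proportional to intensities, exists for models with
age-band effects (restarting at band-crossing birthdays) and as an
independent route: the tests check the two agree with the
matrix-exponential law cell by cell.

What the generator deliberately does not emulate: household clustering,
calibration-weight replication, informative attrition (hooks exist but
are off by default), staggered entry, and mortality. Passing recovery
tests therefore show that the estimator is calibrated under the model's
own assumptions at realistic size and noise — not that those
assumptions hold in any real panel.

## Validation design and problem sizes

The package validates itself at three levels, with sizes chosen to keep
a full test run comfortably interactive:

* deterministic oracles (closed forms, a 60-term series expansion,
  Chapman–Kolmogorov on 100 random generators) at tolerances
  $10^{-8}$–$10^{-10}$;
* a replicated recovery study: 100 synthetic panels of 10 000 subjects
  by six waves from the default truth, requiring absolute bias below
  0.05 on every log-intensity and empirical 95% interval coverage
  (sandwich) between 0.90 and 0.99; plus 50 replicates of 4000
  subjects with a known hazard ratio of 0.6 on the
  never-to-e-cigarette arrow, requiring nominal-rate coverage of the
  true effect;
* qualitative direction checks: with generating effects of known sign
  (ethnic-minority and male contrasts on the never-exit arrows),
  fitted hazard ratios must fall on the correct side of 1.

Exact reproduction of published confidence intervals, baseline count
tables and hazard-ratio values is out of scope: those require the
licensed microdata and its survey weight design. What is reproduced
exactly is the deterministic projection arithmetic — row-normalising
the published one-year matrix and iterating it reproduces the published
three- and five-year percentages to the printed precision
(`verify_printed_projections()`).

## Known limitations

* The likelihood assumes time-homogeneity within covariate strata; the
  `homogeneity` sensitivity analysis probes this by comparing
  consecutive two-wave fits with the pooled fit, but the package does
  not fit calendar-time-varying intensities.
* Gradients and Hessians are numerical; with the full covariate set
  (64 parameters) an adjusted fit costs minutes, not seconds, on large
  panels.
* No misclassification (hidden Markov) layer, no multiple imputation
  of missing covariates, and no frailty terms.
* The default arrow set encodes one reading of the permitted-transition
  topology; users whose application forbids direct movement between
  the two current-use states should supply their own structure and
  refit.
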