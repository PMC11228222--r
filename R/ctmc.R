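#' Validate a transition intensity matrix
#'
#' A valid generator Q has nonnegative off-diagonal entries (zero wherever
#' the structure permits no arrow), each diagonal entry equal to minus the
#' row's off-diagonal sum, and therefore rows summing to zero.
#'
#' @param Q Square numeric matrix of per-year intensities.
#' @param struct Optional `transition_structure`; when supplied, off-arrow
#'   entries must be exactly zero.
#' @param tol Numerical tolerance for the row-sum and sign checks.
#' @return Invisibly, `Q` (with state dimnames attached when `struct` is
#'   given). Throws a validation error listing offending entries otherwise.
#' @export
validate_intensity_matrix <- function(Q, struct = NULL, tol = 1e-8) {
  if (!is.matrix(Q) || nrow(Q) != ncol(Q) || !is.numeric(Q)) {
    stop("Q must be a square numeric matrix")
  }
  n <- nrow(Q)
  off <- Q
  diag(off) <- 0
  bad_neg <- which(off < -tol, arr.ind = TRUE)
  msgs <- character(0)
  if (nrow(bad_neg)) {
    msgs <- c(msgs, paste0("negative off-diagonal at (",
                           bad_neg[, 1], ",", bad_neg[, 2], ")"))
  }
  rs <- rowSums(Q)
  bad_rows <- which(abs(rs) > tol)
  if (length(bad_rows)) {
    msgs <- c(msgs, paste0("row ", bad_rows, " sums to ",
                           signif(rs[bad_rows], 6), " (expected 0)"))
  }
  if (!is.null(struct)) {
    stopifnot(inherits(struct, "transition_structure"))
    if (n != length(struct$states)) {
      stop("Q dimension does not match number of states in structure")
    }
    dimnames(Q) <- list(struct$states, struct$states)
    A <- arrow_matrix(struct)
    off_arrow <- which(!A & abs(off) > tol & row(A) != col(A), arr.ind = TRUE)
    if (nrow(off_arrow)) {
      msgs <- c(msgs, paste0("nonzero intensity on forbidden arrow ",
                             struct$states[off_arrow[, 1]], "->",
                             struct$states[off_arrow[, 2]]))
    }
  }
  if (length(msgs)) {
    stop("invalid intensity matrix: ", paste(msgs, collapse = "; "))
  }
  invisible(Q)
}

#' Transition probability matrix P(t) = exp(tQ)
#'
#' Under a time-homogeneous continuous-time Markov chain with generator Q,
#' the probability of occupying each state after t years given the current
#' state is the matrix exponential of tQ. Computed with a dense scaling and
#' squaring algorithm ([Matrix::expm()]).
#'
#' @param Q Valid intensity matrix (see [validate_intensity_matrix()]).
#' @param t Horizon in years, `t >= 0`.
#' @param struct Optional structure used for validation and dimnames.
#' @return Row-stochastic matrix P(t); `t = 0` gives the identity.
#' @export
#' @examples
#' Q <- rbind(c(-0.5, 0.5), c(0, 0))
#' transition_probability(Q, 2)[1, 2]  # 1 - exp(-1)
transition_probability <- function(Q, t, struct = NULL) {
  validate_intensity_matrix(Q, struct)
  stopifnot(is.numeric(t), length(t) == 1, t >= 0, is.finite(t))
  P <- as.matrix(Matrix::expm(t * Q))
  # guard against tiny negative round-off
  P[P < 0 & P > -1e-12] <- 0
  dimnames(P) <- dimnames(Q)
  P
}

#' Check a matrix is row-stochastic
#' @keywords internal
#' @noRd
.check_stochastic <- function(P, tol = 1e-8) {
  if (!is.matrix(P) || nrow(P) != ncol(P)) stop("P must be square")
  if (any(P < -tol) || any(P > 1 + tol)) {
    stop("transition matrix has entries outside [0, 1]")
  }
  dev <- abs(rowSums(P) - 1)
  if (any(dev > tol)) {
    stop("transition matrix rows do not sum to 1 (max deviation ",
         signif(max(dev), 4), "); renormalise first, e.g. with ",
         "normalise_printed()")
  }
  invisible(P)
}

#' Iterate a one-year transition matrix over k years
#'
#' Multi-year transition probabilities are obtained by repeated
#' multiplication of the one-year matrix, each iteration corresponding to
#' one year.
#'
#' @param P1 Row-stochastic one-year transition matrix.
#' @param k Nonnegative integer number of years.
#' @param tol Row-stochasticity tolerance.
#' @return The matrix power `P1^k`; `k = 0` gives the identity.
#' @export
iterate_annual <- function(P1, k, tol = 1e-8) {
  .check_stochastic(P1, tol)
  stopifnot(length(k) == 1, k >= 0, k == round(k))
  out <- diag(nrow(P1))
  dimnames(out) <- dimnames(P1)
  for (i in seq_len(k)) out <- out %*% P1
  out
}

#' Row-normalise a printed transition matrix
#'
#' Published transition-probability tables are rounded, so rows can sum to
#' slightly more or less than 100%. This divides each row by its sum (and
#' accepts either percentage or probability scale), recording the raw input
#' as an attribute for provenance.
#'
#' @param M Nonnegative square matrix of printed probabilities or
#'   percentages.
#' @return Row-stochastic matrix with attribute `"raw"` holding the input.
#' @export
#' @examples
#' normalise_printed(rbind(c(79.6, 12.2, 8.3), c(10, 80, 10), c(0, 0, 100)))
normalise_printed <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) stop("printed matrix must be square")
  if (any(M < 0)) stop("printed matrix has negative entries")
  rs <- rowSums(M)
  if (any(rs <= 0)) {
    stop("printed matrix has an all-zero row (row ",
         paste(which(rs <= 0), collapse = ", "), ")")
  }
  P <- M / rs
  attr(P, "raw") <- M
  P
}

#' State-occupancy probabilities over annual iterations
#'
#' For a cohort starting in `from`, returns the occupancy distribution over
#' states after each of 1..K annual iterations of the one-year matrix (the
#' `from` row of P1^k).
#'
#' @param P1 Row-stochastic one-year transition matrix with state dimnames.
#' @param from State label of the starting state.
#' @param K Horizon in years, `K >= 1`.
#' @return A data.frame with columns `year` and one column per state; each
#'   row is a probability distribution.
#' @export
occupancy_curve <- function(P1, from, K) {
  .check_stochastic(P1)
  stopifnot(length(K) == 1, K >= 1, K == round(K))
  states <- rownames(P1)
  if (is.null(states)) states <- paste0("S", seq_len(nrow(P1)))
  if (!from %in% states) {
    stop("unknown starting state '", from, "'; states are: ",
         paste(states, collapse = ", "))
  }
  Pk <- P1
  rows <- matrix(NA_real_, K, nrow(P1), dimnames = list(NULL, states))
  for (k in seq_len(K)) {
    rows[k, ] <- Pk[from, ]
    Pk <- Pk %*% P1
  }
  data.frame(year = seq_len(K), rows, check.names = FALSE)
}

#' Published one-year transition percentages for UK youth
#'
#' The one-year unadjusted transition-probability estimates (in percent)
#' between the four nicotine-product-use states for UK 10-25 year-olds,
#' as published for a large household panel cohort. Rows are starting
#' states, columns destination states, in [nicotine_states()] order. Rows
#' can sum to slightly off 100 because the published values are rounded;
#' pass through [normalise_printed()] before projecting. The never-to-
#' non-current cell is the remainder of the never row (the published table
#' reports the other three cells of that row).
#'
#' @return 4x4 numeric matrix of percentages with state dimnames.
#' @export
#' @examples
#' P1 <- normalise_printed(reference_one_year_matrix())
#' round(100 * iterate_annual(P1, 3), 1)
reference_one_year_matrix <- function() {
  path <- system.file("extdata", "uk_youth_one_year_pct.csv",
                      package = "nicomsm", mustWork = TRUE)
  read_matrix_csv(path)
}

#' Read / write a square state-labelled matrix as CSV
#'
#' Matrices are stored with state labels as the header and first column, so
#' files remain self-describing.
#'
#' @param path File path.
#' @param M Matrix with dimnames (for writing).
#' @return `read_matrix_csv` returns a numeric matrix with dimnames.
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  rn <- df[[1]]
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- rn
  storage.mode(M) <- "double"
  if (nrow(M) != ncol(M)) stop("matrix in ", path, " is not square")
  M
}

#' @rdname read_matrix_csv
#' @export
write_matrix_csv <- function(M, path) {
  df <- data.frame(state = rownames(M), M, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# ---- internal: fast transition-probability entries over interval groups ----

# For one generator Q and many interval groups (dt, from, to), compute
# P(dt)[from, to] for every group. Uses the eigendecomposition
# P(dt) = V diag(exp(lambda dt)) V^{-1} when Q is cleanly diagonalisable,
# which vectorises over all groups at once; falls back to one matrix
# exponential per unique dt otherwise.
.tpm_entries <- function(Q, dt, from, to) {
  n <- nrow(Q)
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  use_eigen <- FALSE
  if (!is.null(eg)) {
    Vinv <- tryCatch(solve(eg$vectors), error = function(e) NULL)
    if (!is.null(Vinv)) {
      recon <- Re(eg$vectors %*% diag(eg$values, n) %*% Vinv)
      if (max(abs(recon - Q)) < 1e-9 * max(1, max(abs(Q)))) use_eigen <- TRUE
    }
  }
  if (use_eigen) {
    V <- eg$vectors
    WT <- t(Vinv)                     # WT[s, k] = Vinv[k, s]
    A <- exp(outer(dt, eg$values))    # groups x n, possibly complex
    ent <- Re(rowSums(V[from, , drop = FALSE] * A * WT[to, , drop = FALSE]))
  } else {
    ent <- numeric(length(dt))
    for (u in unique(dt)) {
      P <- as.matrix(Matrix::expm(u * Q))
      # an overflowing exponential can return a non-stochastic result;
      # treat it as an invalid region rather than trusting its entries
      if (anyNA(P) || any(abs(rowSums(P) - 1) > 1e-6)) {
        P[] <- 0
      }
      idx <- which(dt == u)
      ent[idx] <- P[cbind(from[idx], to[idx])]
    }
  }
  # overflow at extreme trial intensities must read as probability zero,
  # never one; then clamp eigenroute round-off
  ent[!is.finite(ent)] <- 0
  pmin(pmax(ent, 0), 1)
}
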