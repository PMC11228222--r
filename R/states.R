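#' The four nicotine product use states
#'
#' Returns the ordered labels of the four analysis states: never use of any
#' nicotine product, non-current use (prior use but none at the interview),
#' current e-cigarette-only use, and current cigarette smoking. The smoking
#' state pools cigarette-only and dual (cigarette plus e-cigarette) use,
#' because transitions between those two are sparse in youth panels and
#' smoking is the state that matters most for health.
#'
#' @return Character vector of length 4, in the canonical order used by all
#'   matrices in this package.
#' @export
#' @examples
#' nicotine_states()
nicotine_states <- function() {
  c("NEVER", "NONCURRENT", "ECIG_ONLY", "SMOKING")
}

#' Default permitted-transition arrows
#'
#' The default instantaneous transition structure: never users can start
#' either product directly; current and non-current users can move among
#' themselves in any direction; nothing re-enters the never state (never use
#' is unrecoverable by definition). Eight arrows in total, including the
#' direct e-cigarette-to-smoking and smoking-to-e-cigarette arrows.
#'
#' @return A two-column data.frame with columns `from` and `to`.
#' @export
default_arrows <- function() {
  data.frame(
    from = c("NEVER", "NEVER", "NONCURRENT", "NONCURRENT",
             "ECIG_ONLY", "ECIG_ONLY", "SMOKING", "SMOKING"),
    to = c("ECIG_ONLY", "SMOKING", "ECIG_ONLY", "SMOKING",
           "NONCURRENT", "SMOKING", "NONCURRENT", "ECIG_ONLY"),
    stringsAsFactors = FALSE
  )
}

#' Construct a permitted-transition structure
#'
#' A transition structure is the set of state labels together with the
#' directed arrows along which the instantaneous transition intensity may be
#' nonzero. Intensities are identically zero off this set.
#'
#' @param states Ordered character vector of state labels.
#' @param arrows Two-column data.frame (`from`, `to`) of permitted arrows.
#' @return An object of class `transition_structure`.
#' @export
#' @examples
#' str4 <- transition_structure()
#' str4
transition_structure <- function(states = nicotine_states(),
                                 arrows = default_arrows()) {
  stopifnot(is.character(states), length(states) >= 2, !anyDuplicated(states))
  arrows <- as.data.frame(arrows, stringsAsFactors = FALSE)
  if (!all(c("from", "to") %in% names(arrows))) {
    stop("`arrows` must have columns 'from' and 'to'")
  }
  arrows <- arrows[, c("from", "to")]
  bad <- !(arrows$from %in% states) | !(arrows$to %in% states)
  if (any(bad)) {
    stop("arrows reference unknown states: ",
         paste(sprintf("%s->%s", arrows$from[bad], arrows$to[bad]),
               collapse = ", "))
  }
  if (any(arrows$from == arrows$to)) {
    stop("self-arrows are not permitted in a transition structure")
  }
  if (anyDuplicated(paste(arrows$from, arrows$to))) {
    stop("duplicate arrows in structure")
  }
  structure(
    list(states = states, arrows = arrows),
    class = "transition_structure"
  )
}

#' @export
print.transition_structure <- function(x, ...) {
  cat("Transition structure with", length(x$states), "states:\n ",
      paste(x$states, collapse = ", "), "\n")
  cat("Permitted arrows (", nrow(x$arrows), "):\n", sep = "")
  for (i in seq_len(nrow(x$arrows))) {
    cat("  ", x$arrows$from[i], "->", x$arrows$to[i], "\n")
  }
  invisible(x)
}

#' Logical adjacency matrix of a transition structure
#'
#' @param struct A `transition_structure`.
#' @return Square logical matrix, TRUE where an arrow is permitted.
#' @export
arrow_matrix <- function(struct) {
  stopifnot(inherits(struct, "transition_structure"))
  n <- length(struct$states)
  A <- matrix(FALSE, n, n, dimnames = list(struct$states, struct$states))
  A[cbind(struct$arrows$from, struct$arrows$to)] <- TRUE
  A
}

#' Reachability between states under a structure
#'
#' TRUE at (r, s) when state s can be reached from r along permitted arrows
#' (including r itself). Observed interval patterns outside this set have
#' probability exactly zero under any intensity model on the structure.
#'
#' @param struct A `transition_structure`.
#' @return Square logical matrix.
#' @export
reachability_matrix <- function(struct) {
  A <- arrow_matrix(struct)
  n <- nrow(A)
  R <- A | diag(TRUE, n)
  # transitive closure; n is tiny so repeated boolean squaring is fine
  for (i in seq_len(ceiling(log2(max(n, 2))) + 1)) {
    R <- (R %*% R) > 0
  }
  dimnames(R) <- dimnames(A)
  R
}

#' Read / write a transition structure as JSON
#'
#' The JSON form is a list of `{"from": ..., "to": ...}` arrow objects plus
#' the ordered state labels, so that the permitted structure stays
#' user-auditable alongside any analysis artifact.
#'
#' @param path File path.
#' @param struct A `transition_structure` (for writing).
#' @return `read_structure_json` returns a `transition_structure`.
#' @export
read_structure_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  transition_structure(states = obj$states,
                       arrows = as.data.frame(obj$arrows))
}

#' @rdname read_structure_json
#' @export
write_structure_json <- function(struct, path) {
  stopifnot(inherits(struct, "transition_structure"))
  jsonlite::write_json(
    list(states = struct$states, arrows = struct$arrows),
    path, auto_unbox = FALSE, pretty = TRUE
  )
  invisible(path)
}
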