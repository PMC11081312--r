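#' Discrete probability vector over named outcome states
#'
#' A `prob_vector` is a normalized distribution over the named states of a
#' discrete outcome variable. It is the basic currency of the combination
#' formulas: priors, single-source posteriors and combined posteriors are
#' all `prob_vector`s. States are matched by label, never by position.
#'
#' Inputs whose probabilities sum to 1 within `tol` are renormalized;
#' anything further off is rejected as malformed.
#'
#' @param probs Named numeric vector of probabilities, one per state.
#'   Names are the state labels and must be unique; at least two states
#'   are required.
#' @param tol Tolerance on the sum-to-one constraint (default `1e-12`).
#' @return A `prob_vector` object (a named numeric vector).
#' @examples
#' prob_vector(c("1" = 0.4, "0" = 0.6))
#' @export
prob_vector <- function(probs, tol = 1e-12) {
  if (!is.numeric(probs)) stop("`probs` must be numeric")
  nm <- names(probs)
  if (is.null(nm) || any(!nzchar(nm))) {
    stop("`probs` must be fully named by state labels")
  }
  if (anyDuplicated(nm)) stop("state labels must be unique")
  if (length(probs) < 2L) stop("a prob_vector needs at least 2 states")
  if (anyNA(probs)) stop("probabilities must not be NA")
  if (any(probs < -tol) || any(probs > 1 + tol)) {
    stop("probabilities must lie in [0, 1]")
  }
  probs <- pmin(pmax(probs, 0), 1)
  s <- sum(probs)
  if (abs(s - 1) > tol) {
    stop(sprintf("probabilities must sum to 1 (got %.15g)", s))
  }
  structure(probs / s, class = "prob_vector")
}

#' @export
print.prob_vector <- function(x, ...) {
  cat("<prob_vector over", length(x), "states>\n")
  print(unclass(x), ...)
  invisible(x)
}

is_prob_vector <- function(x) inherits(x, "prob_vector")

#' Coerce to a probability vector
#'
#' @param x Named numeric vector or `prob_vector`.
#' @param tol Sum-to-one tolerance passed to [prob_vector()].
#' @return A `prob_vector`.
#' @export
as_prob_vector <- function(x, tol = 1e-12) {
  if (is_prob_vector(x)) return(x)
  prob_vector(x, tol = tol)
}

# Align a set of prob_vectors on a shared state set; error on mismatch.
align_states <- function(pvs, what = "probability vectors") {
  pvs <- lapply(pvs, as_prob_vector)
  ref <- names(pvs[[1L]])
  for (pv in pvs[-1L]) {
    if (!setequal(names(pv), ref)) {
      stop("state-set mismatch between ", what, ": {",
           paste(ref, collapse = ","), "} vs {",
           paste(names(pv), collapse = ","), "}")
    }
  }
  lapply(pvs, function(pv) {
    structure(unclass(pv)[ref], class = "prob_vector")
  })
}
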