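#' One vector of correlated uniform samples
#'
#' Two generators for positively correlated Uniform(0,1) samples, used to
#' induce correlation between otherwise independent binary outcomes.
#' Both start from N independent uniforms `u_j` and one shared uniform
#' `eta`, with a mixing parameter `alpha` in [0, 1]:
#' \itemize{
#'   \item method 1 (reset): `r_j = eta` with probability `alpha`,
#'     otherwise `r_j = u_j`. Each `r_j` remains marginally Uniform(0,1),
#'     so downstream thresholding preserves target marginals exactly.
#'   \item method 2 (shrink): `r_j = alpha*eta + (1-alpha)*u_j`. The
#'     samples converge on a common point as `alpha` grows, but the
#'     mixture is no longer Uniform(0,1), so thresholded marginals are
#'     mildly distorted; this is implemented as defined, not corrected.
#' }
#'
#' @param n_events Number of correlated samples N (at least 1).
#' @param alpha Correlation parameter in [0, 1].
#' @param method `"1"` (reset) or `"2"` (shrink).
#' @return Numeric vector of N values in [0, 1].
#' @export
correlated_uniforms <- function(n_events, alpha, method = c("1", "2")) {
  method <- match.arg(as.character(method), c("1", "2"))
  stopifnot(n_events >= 1, alpha >= 0, alpha <= 1)
  eta <- stats::runif(1)
  u <- stats::runif(n_events)
  if (method == "1") {
    reset <- stats::runif(n_events) < alpha
    ifelse(reset, eta, u)
  } else {
    alpha * eta + (1 - alpha) * u
  }
}

#' Simulate correlated binary outcomes at target marginal probabilities
#'
#' Draws `n_draws` rows of N binary events. Within each row, event j is 1
#' iff a correlated uniform sample `r_j` falls below its probability
#' `p[j]`; the shared component of the uniforms (see
#' [correlated_uniforms()]) makes events within a row positively
#' correlated while (for method 1) leaving each column's marginal
#' probability at exactly `p[j]`. A fresh shared sample and fresh reset
#' coins are drawn for every row.
#'
#' @param p Vector of N marginal probabilities in [0, 1].
#' @param n_draws Number of rows to simulate.
#' @param alpha Correlation parameter in [0, 1].
#' @param method `"1"` (reset) or `"2"` (shrink); see
#'   [correlated_uniforms()].
#' @param seed Optional integer seed; omit to use the current RNG stream.
#' @return Integer matrix (`n_draws` x N) of 0/1 outcomes, with the
#'   target probabilities attached as attribute `"p"`.
#' @examples
#' m <- sample_outcomes(c(0.7, 0.7), n_draws = 1000, alpha = 0.5, seed = 1)
#' colMeans(m)
#' @export
sample_outcomes <- function(p, n_draws, alpha, method = c("1", "2"),
                            seed = NULL) {
  method <- match.arg(as.character(method), c("1", "2"))
  stopifnot(all(p >= 0 & p <= 1), n_draws >= 1, alpha >= 0, alpha <= 1)
  if (!is.null(seed)) set.seed(seed)
  n_ev <- length(p)
  eta <- stats::runif(n_draws)
  u <- matrix(stats::runif(n_draws * n_ev), nrow = n_draws)
  r <- if (method == "1") {
    reset <- matrix(stats::runif(n_draws * n_ev), nrow = n_draws) < alpha
    ifelse(reset, eta[row(u)], u)
  } else {
    alpha * eta + (1 - alpha) * u
  }
  out <- matrix(as.integer(r < matrix(p, n_draws, n_ev, byrow = TRUE)),
                nrow = n_draws)
  attr(out, "p") <- p
  out
}

#' Phi (binary Pearson) correlation matrix of an outcome matrix
#'
#' Pearson correlation between all pairs of binary columns — the phi
#' coefficient. Columns that are constant have undefined correlation and
#' yield `NA` cells with a warning.
#'
#' @param m 0/1 matrix, rows = draws, columns = events (at least 2 rows).
#' @return Symmetric N x N correlation matrix with unit diagonal.
#' @export
phi_correlation <- function(m) {
  stopifnot(is.matrix(m), nrow(m) >= 2L)
  sds <- apply(m, 2L, stats::sd)
  const <- sds == 0
  phi <- suppressWarnings(stats::cor(m))
  diag(phi) <- 1
  if (any(const)) {
    warning("constant column(s) ", paste(which(const), collapse = ", "),
            ": phi undefined (NA)")
  }
  phi
}

#' Mean off-diagonal phi correlation
#'
#' Scalar summary of the pairwise correlation among events: the mean of
#' the off-diagonal entries of [phi_correlation()], `NA` cells dropped.
#'
#' @inheritParams phi_correlation
#' @return A single correlation value.
#' @export
mean_phi <- function(m) {
  phi <- suppressWarnings(phi_correlation(m))
  mean(phi[row(phi) != col(phi)], na.rm = TRUE)
}
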