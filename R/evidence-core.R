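#' Combine two conditionally independent sources of evidence
#'
#' Given the posterior distribution of an outcome variable C under each of
#' two evidence sources, `P(C|A)` and `P(C|B)`, and the prior `P(C)`, this
#' computes the joint posterior `P(C|A,B)` that holds exactly when A and B
#' are conditionally independent given C:
#' \deqn{P(C=c|A,B) \propto \frac{P(C=c|A)\,P(C=c|B)}{P(C=c)}.}
#' No three-way measurement of (A, B, C) is needed; the two pairwise
#' relationships and the prior suffice.
#'
#' A state with prior probability zero but positive evidence posterior is
#' inconsistent (the conditionals can never exceed support of the prior)
#' and raises an error. If every unnormalized score is zero the evidence is
#' jointly contradictory, which is also an error rather than a silent NaN.
#'
#' @param post_a,post_b Posteriors `P(C|A)` and `P(C|B)` as
#'   [prob_vector()]s (or named numerics) over the same states.
#' @param prior Prior `P(C)` over the same states.
#' @return A `combination_result`: list with `posterior` (a
#'   `prob_vector`) and `f_values` (the unnormalized per-state scores).
#' @examples
#' # Frequency-tree worked example: prior 0.4, both posteriors 0.6
#' combine_two(c("1" = 0.6, "0" = 0.4),
#'             c("1" = 0.6, "0" = 0.4),
#'             prior = c("1" = 0.4, "0" = 0.6))$posterior[["1"]]  # 27/35
#' @seealso [combine_many()] for N sources, [posterior_odds()],
#'   [linear_approx()], [combine_exclusive()]
#' @export
combine_two <- function(post_a, post_b, prior) {
  combine_many(list(post_a, post_b), prior)
}

#' Combine N conditionally independent sources of evidence
#'
#' Generalization of [combine_two()] to any number of sources and any
#' number of outcome states: with posteriors `P(C|E^(k))`, k = 1..N, and
#' prior `P(C)`, the unnormalized score for state c is
#' \deqn{f(c) = \frac{\prod_k P(C=c\mid E^{(k)})}{P(C=c)^{N-1}}}
#' and the combined posterior is `f` normalized over states. With N = 2
#' this is identical to [combine_two()]; with N = 1 it returns the single
#' posterior unchanged.
#'
#' @param posts List of posteriors, one [prob_vector()] per source.
#' @param prior Prior `P(C)` over the same states.
#' @return A `combination_result` (see [combine_two()]).
#' @export
combine_many <- function(posts, prior) {
  if (!is.list(posts) || length(posts) < 1L) {
    stop("`posts` must be a non-empty list of probability vectors")
  }
  aligned <- align_states(c(posts, list(prior)), "posteriors and prior")
  n <- length(posts)
  prior <- aligned[[n + 1L]]
  prod_post <- Reduce(`*`, lapply(aligned[seq_len(n)], unclass))

  bad <- prior == 0 & prod_post > 0
  if (any(bad)) {
    stop("zero-prior state(s) with positive evidence posterior: ",
         paste(names(prior)[bad], collapse = ", "),
         " (conditionals cannot exceed the prior's support)")
  }
  f <- ifelse(prior == 0, 0, prod_post / unclass(prior)^(n - 1L))
  names(f) <- names(prior)
  if (all(f == 0)) {
    stop("degenerate evidence: all combined scores are zero ",
         "(the sources jointly contradict every state)")
  }
  structure(
    list(posterior = prob_vector(f / sum(f)), f_values = f),
    class = "combination_result"
  )
}

#' @export
print.combination_result <- function(x, ...) {
  cat("<combination_result>\nposterior:\n")
  print(unclass(x$posterior), ...)
  invisible(x)
}

#' Posterior odds of two outcome states under combined evidence
#'
#' Odds form of the two-source combination rule: the posterior odds of
#' `state1` against `state0` given both sources is the product of the two
#' single-source odds times the *inverted* prior odds,
#' \deqn{\frac{P(1|A,B)}{P(0|A,B)} =
#'   \frac{P(1|A)}{P(0|A)}\frac{P(1|B)}{P(0|B)}\frac{P(0)}{P(1)}.}
#' Equals the ratio of the corresponding [combine_two()] posterior
#' entries.
#'
#' @inheritParams combine_two
#' @param state1,state0 Labels of the numerator and denominator states.
#' @return A single odds ratio.
#' @export
posterior_odds <- function(post_a, post_b, prior, state1, state0) {
  aligned <- align_states(list(post_a, post_b, prior))
  for (pv in aligned) {
    if (!all(c(state1, state0) %in% names(pv))) {
      stop("states ", state1, " and ", state0, " must both be present")
    }
  }
  a <- aligned[[1L]]; b <- aligned[[2L]]; pr <- aligned[[3L]]
  denoms <- c(a[[state0]], b[[state0]], pr[[state1]])
  if (any(denoms == 0)) {
    stop("zero probability in an odds denominator (states ",
         state0, "/", state1, ")")
  }
  (a[[state1]] / a[[state0]]) * (b[[state1]] / b[[state0]]) *
    (pr[[state0]] / pr[[state1]])
}

#' Linear approximation to the two-source combination
#'
#' For small deviations of the single-source posteriors from the prior,
#' combining evidence is simply additive: with `P(C=1|A) = P(C=1) + eps_A`
#' and `P(C=1|B) = P(C=1) + eps_B`,
#' \deqn{P(C=1|A,B) \approx P(C=1) + \epsilon_A + \epsilon_B.}
#' The approximation error is second order in the deviations and the
#' result is intentionally *not* clipped to [0, 1]: it is only valid when
#' the deviations are small and the prior is well away from 0 and 1.
#' This helper is pedagogical/diagnostic; no other routine relies on it.
#'
#' @param post_a_1,post_b_1 Single-source posterior probabilities of the
#'   focal state.
#' @param prior_1 Prior probability of the focal state.
#' @return Approximate combined probability (possibly outside [0, 1]).
#' @examples
#' linear_approx(0.6, 0.6, 0.4)  # 0.8 (exact answer is 27/35)
#' @export
linear_approx <- function(post_a_1, post_b_1, prior_1) {
  stopifnot(post_a_1 >= 0, post_a_1 <= 1,
            post_b_1 >= 0, post_b_1 <= 1,
            prior_1 >= 0, prior_1 <= 1)
  prior_1 + (post_a_1 - prior_1) + (post_b_1 - prior_1)
}

#' Combine two exclusively presented cues (multisensory form)
#'
#' In a cue-integration experiment the unisensory conditions measure
#' `P(correct | A alone)` and `P(correct | V alone)` — not `P(correct|A)`
#' with V unknown — so the plain two-source rule does not apply directly.
#' The correctly matched version replaces the prior with the no-cue
#' (chance) performance:
#' \deqn{P(1|1,1) = \frac{p_A p_V}
#'   {p_A p_V + (1-p_A)(1-p_V)\,\frac{p_0}{1-p_0}}}
#' where `p_A`, `p_V` are the unisensory proportions correct and `p_0` is
#' chance performance. The result is bounded below by the better single
#' cue (when both are at or above chance) and above by 1.
#'
#' @param p_a_only Proportion correct with cue A alone.
#' @param p_v_only Proportion correct with cue V alone (may be a vector,
#'   e.g. one value per stimulus intensity).
#' @param p_chance Chance performance, strictly inside (0, 1).
#' @return Predicted proportion correct with both cues (vectorized over
#'   `p_v_only`).
#' @examples
#' combine_exclusive(0.75, 0.75, 0.5)  # 0.9
#' @export
combine_exclusive <- function(p_a_only, p_v_only, p_chance) {
  if (length(p_chance) != 1L || is.na(p_chance) ||
      p_chance <= 0 || p_chance >= 1) {
    stop("`p_chance` must lie strictly inside (0, 1)")
  }
  stopifnot(all(p_a_only >= 0 & p_a_only <= 1),
            all(p_v_only >= 0 & p_v_only <= 1))
  num <- p_a_only * p_v_only
  den <- num + (1 - p_a_only) * (1 - p_v_only) * p_chance / (1 - p_chance)
  if (any(den == 0)) {
    stop("degenerate evidence: both cues certain of the incorrect outcome")
  }
  num / den
}
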