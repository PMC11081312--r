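#' Characteristics of a diagnostic test
#'
#' Sensitivity `s+ = P(T=+|D=1)`, specificity `s- = P(T=-|D=0)`, and the
#' disease prevalence `P(D=1)` — everything needed to turn test outcomes
#' into predictive values.
#'
#' @param sensitivity,specificity,prevalence Probabilities in [0, 1].
#' @return A `test_characteristics` object.
#' @export
test_characteristics <- function(sensitivity, specificity, prevalence) {
  for (v in c(sensitivity, specificity, prevalence)) {
    stopifnot(length(v) == 1L, v >= 0, v <= 1)
  }
  structure(list(sensitivity = sensitivity, specificity = specificity,
                 prevalence = prevalence),
            class = "test_characteristics")
}

#' Predictive values of a diagnostic test
#'
#' Bayes inversion of sensitivity/specificity against the prevalence:
#' \deqn{r^+ = \frac{s^+ P(D=1)}{s^+ P(D=1) + (1-s^-) P(D=0)}, \quad
#'       r^- = \frac{s^- P(D=0)}{s^- P(D=0) + (1-s^+) P(D=1)}.}
#' `r_plus` (PPV) is the probability the disease is present given a
#' positive test; `r_minus` (NPV) that it is absent given a negative one.
#'
#' @param tc A [test_characteristics()].
#' @return List with `r_plus` and `r_minus`.
#' @examples
#' predictive_values(test_characteristics(0.5, 0.75, 0.5))  # 2/3, 0.6
#' @export
predictive_values <- function(tc) {
  stopifnot(inherits(tc, "test_characteristics"))
  sp <- tc$sensitivity; sm <- tc$specificity
  p1 <- tc$prevalence; p0 <- 1 - p1
  den_pos <- sp * p1 + (1 - sm) * p0
  den_neg <- sm * p0 + (1 - sp) * p1
  if (den_pos == 0) stop("test is never positive: PPV undefined")
  if (den_neg == 0) stop("test is never negative: NPV undefined")
  list(r_plus = sp * p1 / den_pos, r_minus = sm * p0 / den_neg)
}

#' Posterior disease probability after repeated tests
#'
#' Probability that the disease is present given that `n_pos` of
#' `n_total` conditionally independent repetitions of the same test were
#' positive. Because every repetition shares the same predictive values,
#' the N-source combination rule collapses to
#' \deqn{P(D=1|n\,\mathrm{of}\,N\,+) =
#'   \frac{(r^+)^n (1-r^-)^{N-n}}
#'        {(r^+)^n (1-r^-)^{N-n} + (1-r^+)^n (r^-)^{N-n}
#'         \left[\frac{P(D=1)}{P(D=0)}\right]^{N-1}}.}
#' Identical (to machine precision) to [combine_many()] applied to the N
#' per-test posteriors.
#'
#' @param pv Predictive values, as returned by [predictive_values()]
#'   (list with `r_plus`, `r_minus`).
#' @param prior Disease prevalence `P(D=1)`, strictly inside (0, 1).
#' @param n_pos Number of positive tests (0..`n_total`).
#' @param n_total Total number of test repetitions (vectorization over
#'   `n_pos` is supported).
#' @return `P(D=1 | n_pos of n_total positive)`, same length as `n_pos`.
#' @examples
#' pv <- predictive_values(test_characteristics(0.5, 0.75, 0.5))
#' repeated_test_posterior(pv, 0.5, n_pos = 4, n_total = 4)  # 16/17
#' @export
repeated_test_posterior <- function(pv, prior, n_pos, n_total) {
  stopifnot(prior > 0, prior < 1, n_total >= 1,
            all(n_pos >= 0), all(n_pos <= n_total))
  rp <- pv$r_plus; rm_ <- pv$r_minus
  f1 <- rp^n_pos * (1 - rm_)^(n_total - n_pos)
  f0 <- (1 - rp)^n_pos * rm_^(n_total - n_pos) *
    (prior / (1 - prior))^(n_total - 1)
  if (any(f1 + f0 == 0)) {
    stop("degenerate predictive values: posterior is 0/0 for some n_pos")
  }
  f1 / (f1 + f0)
}

#' Likelihood of each number of positive tests
#'
#' Under conditional independence, the number of positive results in
#' `n_total` repetitions is Binomial(`n_total`, `s+`) when the disease is
#' present and Binomial(`n_total`, `1 - s-`) when it is absent.
#'
#' @param tc A [test_characteristics()].
#' @param n_total Number of test repetitions.
#' @param disease 1 (present) or 0 (absent).
#' @return Probability vector over n = 0..`n_total` (sums to 1).
#' @export
n_positive_likelihood <- function(tc, n_total, disease) {
  stopifnot(inherits(tc, "test_characteristics"), n_total >= 1,
            disease %in% c(0, 1))
  p <- if (disease == 1) tc$sensitivity else 1 - tc$specificity
  stats::setNames(stats::dbinom(0:n_total, n_total, p),
                  as.character(0:n_total))
}

#' Simulate repeated, possibly correlated, diagnostic tests
#'
#' Draws `n_subjects` disease states from the prevalence, then for each
#' subject draws `n_total` test outcomes whose per-test marginal is `s+`
#' (diseased) or `1 - s-` (healthy) but which are correlated *within*
#' subject via [sample_outcomes()] — test repetitions are conditionally
#' independent given the disease state only when `alpha = 0`. The
#' empirical posterior `P(D=1 | n positive)` per bin is paired with the
#' closed-form prediction of [repeated_test_posterior()]; at `alpha = 0`
#' the pairs sit on the diagonal up to Monte-Carlo error, and growing
#' `alpha` pushes them off it.
#'
#' @param tc A [test_characteristics()].
#' @param n_total Number of test repetitions per subject.
#' @param alpha Within-subject correlation parameter in [0, 1].
#' @param method Correlated-uniform generator, `"1"` or `"2"`.
#' @param n_subjects Number of simulated subjects (default `1e5`).
#' @param seed Optional integer seed.
#' @return Data frame with one row per number-of-positives bin:
#'   `n_pos`, `n_obs`, `empirical_pos`, `empirical_neg`,
#'   `predicted_pos`, `predicted_neg`. Empty bins carry `NA` empirical
#'   values and trigger a warning.
#' @export
simulate_repeated_tests <- function(tc, n_total, alpha = 0, method = "1",
                                    n_subjects = 1e5, seed = NULL) {
  stopifnot(inherits(tc, "test_characteristics"), n_total >= 1,
            n_subjects >= 1)
  if (!is.null(seed)) set.seed(seed)
  disease <- stats::rbinom(n_subjects, 1L, tc$prevalence)
  n_dis <- sum(disease == 1L); n_hea <- n_subjects - n_dis
  n_pos <- integer(n_subjects)
  if (n_dis > 0) {
    m <- sample_outcomes(rep(tc$sensitivity, n_total), n_dis,
                         alpha, method)
    n_pos[disease == 1L] <- rowSums(m)
  }
  if (n_hea > 0) {
    m <- sample_outcomes(rep(1 - tc$specificity, n_total), n_hea,
                         alpha, method)
    n_pos[disease == 0L] <- rowSums(m)
  }
  pv <- predictive_values(tc)
  ns <- 0:n_total
  n_obs <- vapply(ns, function(k) sum(n_pos == k), 0L)
  emp <- vapply(ns, function(k) {
    if (sum(n_pos == k) == 0) NA_real_ else mean(disease[n_pos == k])
  }, 0)
  if (any(n_obs == 0)) {
    warning("empty number-of-positives bin(s): ",
            paste(ns[n_obs == 0], collapse = ", "),
            "; empirical posterior is NA there")
  }
  pred <- repeated_test_posterior(pv, tc$prevalence, ns, n_total)
  data.frame(n_pos = ns, n_obs = n_obs,
             empirical_pos = emp, empirical_neg = 1 - emp,
             predicted_pos = pred, predicted_neg = 1 - pred)
}
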