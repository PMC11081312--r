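#' Probability that a binary biomarker is in state 1 at a given age
#'
#' Each aging biomarker is modeled as a binary variable whose probability
#' of having switched to state 1 rises smoothly with chronological age
#' `a` along an error-function sigmoid,
#' \deqn{P(B=1\mid a) = \tfrac12\left(1 +
#'   \mathrm{erf}\!\left(\frac{a-\alpha}{\sqrt{2}\,\sigma}\right)\right)
#'   = \Phi\!\left(\frac{a-\alpha}{\sigma}\right),}
#' with `midpoint` (the age at which the probability crosses 0.5) and
#' `steepness` (the transition width, in years) as the two parameters.
#'
#' @param a Age(s) in years (vectorized).
#' @param midpoint Midpoint age alpha, years.
#' @param steepness Transition width sigma, years (> 0).
#' @return Probability in (0, 1), same length as `a`.
#' @examples
#' biomarker_state_prob(50, midpoint = 50, steepness = 10)  # 0.5
#' @export
biomarker_state_prob <- function(a, midpoint, steepness) {
  stopifnot(steepness > 0)
  stats::pnorm((a - midpoint) / steepness)
}

#' Draw a random set of biomarker response-curve parameters
#'
#' Convenience sampler producing a diversity of response curves:
#' midpoints uniform on `midpoint_range` and steepnesses uniform on
#' `steepness_range`. The `"steep"` preset narrows the transitions to
#' 1-5 years, mimicking markers that switch state abruptly.
#'
#' @param n_markers Number of biomarkers.
#' @param midpoint_range Range of midpoint ages (default 15-85 years).
#' @param steepness_range Range of transition widths (default 4-20
#'   years); ignored when `preset = "steep"`.
#' @param preset `"default"` or `"steep"`.
#' @param seed Optional integer seed.
#' @return Data frame with columns `midpoint`, `steepness`.
#' @export
sample_biomarker_params <- function(n_markers,
                                    midpoint_range = c(15, 85),
                                    steepness_range = c(4, 20),
                                    preset = c("default", "steep"),
                                    seed = NULL) {
  preset <- match.arg(preset)
  stopifnot(n_markers >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (preset == "steep") steepness_range <- c(1, 5)
  data.frame(
    midpoint = stats::runif(n_markers, midpoint_range[1], midpoint_range[2]),
    steepness = stats::runif(n_markers, steepness_range[1], steepness_range[2])
  )
}

#' Build a biomarker panel over a discrete age grid
#'
#' Assembles everything needed for age inference from a set of biomarker
#' response curves: the per-age curves `P(B_k=1|a)`, the marker priors
#' `P(B_k=1) = sum_a P(B_k=1|a) P(a)`, and the Bayes-inverted per-marker
#' posteriors `P(a|B_k=s) \propto P(B_k=s|a) P(a)`. The default age grid
#' is the integers 0..100 with a flat prior (1/101 per year).
#'
#' @param params Data frame with columns `midpoint` and `steepness`, one
#'   row per marker (e.g. from [sample_biomarker_params()]).
#' @param age_grid Ordered numeric vector of ages.
#' @param age_prior Optional [prob_vector()] over the grid (named by
#'   age); default flat.
#' @return A `biomarker_panel`: list with `params`, `age_grid`,
#'   `age_prior`, `curves` (ages x markers matrix of `P(B=1|a)`),
#'   `p_state1` (marker priors), and `posteriors` — a list with matrices
#'   `state1`/`state0` of `P(a|B_k=s)` (ages x markers).
#' @export
build_panel <- function(params, age_grid = 0:100, age_prior = NULL) {
  stopifnot(is.data.frame(params),
            all(c("midpoint", "steepness") %in% names(params)),
            nrow(params) >= 1, length(age_grid) >= 2)
  age_lab <- as.character(age_grid)
  if (is.null(age_prior)) {
    age_prior <- prob_vector(stats::setNames(
      rep(1 / length(age_grid), length(age_grid)), age_lab))
  } else {
    age_prior <- as_prob_vector(age_prior)
    if (!setequal(names(age_prior), age_lab)) {
      stop("`age_prior` states must match the age grid")
    }
    age_prior <- structure(unclass(age_prior)[age_lab],
                           class = "prob_vector")
  }
  n_m <- nrow(params)
  curves <- vapply(seq_len(n_m), function(k) {
    biomarker_state_prob(age_grid, params$midpoint[k], params$steepness[k])
  }, numeric(length(age_grid)))
  rownames(curves) <- age_lab
  pr <- as.numeric(age_prior)
  p1 <- as.numeric(crossprod(curves, pr))
  if (any(p1 <= 0) || any(p1 >= 1)) {
    stop("marker(s) ", paste(which(p1 <= 0 | p1 >= 1), collapse = ", "),
         " never/always in state 1 on this grid: uninvertible")
  }
  post1 <- sweep(curves * pr, 2L, p1, `/`)
  post0 <- sweep((1 - curves) * pr, 2L, 1 - p1, `/`)
  rownames(post1) <- rownames(post0) <- age_lab
  structure(
    list(params = params, age_grid = age_grid, age_prior = age_prior,
         curves = curves, p_state1 = p1,
         posteriors = list(state1 = post1, state0 = post0)),
    class = "biomarker_panel"
  )
}

#' @export
print.biomarker_panel <- function(x, ...) {
  cat("<biomarker_panel:", nrow(x$params), "markers over ages",
      min(x$age_grid), "-", max(x$age_grid), ">\n")
  print(x$params, ...)
  invisible(x)
}

#' Posterior age distribution given a biomarker state vector
#'
#' Combines the per-marker inverted posteriors `P(a|B_k = s_k)` with the
#' age prior through the N-source combination rule (see
#' [combine_many()]): the inferred "biological age" distribution under
#' the assumption that the markers are conditionally independent given
#' age.
#'
#' @param panel A [build_panel()] result.
#' @param state Binary vector (0/1), one entry per marker.
#' @return A [prob_vector()] over the age grid.
#' @export
age_posterior <- function(panel, state) {
  stopifnot(inherits(panel, "biomarker_panel"),
            length(state) == nrow(panel$params),
            all(state %in% c(0, 1)))
  age_lab <- as.character(panel$age_grid)
  posts <- lapply(seq_along(state), function(k) {
    m <- if (state[k] == 1) panel$posteriors$state1 else panel$posteriors$state0
    prob_vector(stats::setNames(m[, k], age_lab))
  })
  combine_many(posts, panel$age_prior)$posterior
}

#' Predicted probability of a biomarker state vector at each age
#'
#' Under conditional independence, `P(sv | a) = prod_k P(B_k = sv_k | a)`.
#'
#' @inheritParams age_posterior
#' @return Numeric vector over the age grid.
#' @export
state_vector_prob <- function(panel, state) {
  stopifnot(inherits(panel, "biomarker_panel"),
            length(state) == nrow(panel$params))
  pk <- panel$curves
  pk[, state == 0] <- 1 - pk[, state == 0, drop = FALSE]
  stats::setNames(apply(pk, 1L, prod), as.character(panel$age_grid))
}

#' Congruent biomarker state vectors
#'
#' With monotonically rising response curves, aging flips markers to 1 in
#' midpoint order, so the "congruent" state vectors are the prefixes of
#' ones in that order: all zeros, the earliest marker on, the two
#' earliest on, ..., all ones — N+1 vectors for N markers.
#'
#' @param panel A [build_panel()] result.
#' @return List of N+1 binary vectors (in original marker order).
#' @export
congruent_states <- function(panel) {
  stopifnot(inherits(panel, "biomarker_panel"))
  n <- nrow(panel$params)
  ord <- order(panel$params$midpoint)
  lapply(0:n, function(k) {
    s <- integer(n)
    s[ord[seq_len(k)]] <- 1L
    s
  })
}

#' Simulate a cohort of (possibly correlated) biomarker readouts
#'
#' For each age on the panel's grid, draws `n_per_age` subjects whose
#' marker states are sampled with per-marker probability `P(B_k=1|a)`
#' but correlated within subject via [sample_outcomes()]. At
#' `alpha = 0` the markers are conditionally independent given age by
#' construction; `alpha > 0` violates the assumption while (method 1)
#' preserving each marker's response curve.
#'
#' @param panel A [build_panel()] result.
#' @param alpha Within-subject correlation parameter in [0, 1].
#' @param method Correlated-uniform generator, `"1"` or `"2"`.
#' @param n_per_age Subjects simulated at each grid age.
#' @param seed Optional integer seed.
#' @return A `biomarker_cohort`: list with `age` (vector, one entry per
#'   subject) and `states` (subjects x markers 0/1 matrix).
#' @export
simulate_cohort <- function(panel, alpha = 0, method = "1",
                            n_per_age = 1000, seed = NULL) {
  stopifnot(inherits(panel, "biomarker_panel"), n_per_age >= 1)
  if (!is.null(seed)) set.seed(seed)
  n_age <- length(panel$age_grid)
  states <- lapply(seq_len(n_age), function(i) {
    sample_outcomes(panel$curves[i, ], n_per_age, alpha, method)
  })
  structure(
    list(age = rep(panel$age_grid, each = n_per_age),
         states = do.call(rbind, states),
         alpha = alpha, method = method, n_per_age = n_per_age),
    class = "biomarker_cohort"
  )
}

#' Average within-age marker correlation matrix of a cohort
#'
#' Phi correlations are computed among markers at each age separately
#' (so that age-driven covariation does not masquerade as violation of
#' conditional independence) and then averaged across ages.
#'
#' @param cohort A [simulate_cohort()] result.
#' @return N x N matrix of age-averaged phi coefficients.
#' @export
cohort_phi <- function(cohort) {
  stopifnot(inherits(cohort, "biomarker_cohort"))
  ages <- unique(cohort$age)
  mats <- lapply(ages, function(a) {
    suppressWarnings(phi_correlation(cohort$states[cohort$age == a, ,
                                                   drop = FALSE]))
  })
  avg <- Reduce(`+`, lapply(mats, function(m) {
    m[is.na(m)] <- 0; m
  })) / Reduce(`+`, lapply(mats, function(m) (!is.na(m)) * 1))
  diag(avg) <- 1
  avg
}

#' Conditional-independence stress test on a simulated cohort
#'
#' Two paired comparisons between the conditional-independence
#' predictions and the simulated cohort:
#' \itemize{
#'   \item `state_given_age`: for each state vector and age, the
#'     predicted `P(sv|a)` (product of per-marker curves) against the
#'     empirical frequency of `sv` among subjects of that age;
#'   \item `age_given_state`: for each state vector, the combined
#'     posterior `P(a|sv)` against the empirical proportion of each age
#'     among subjects showing `sv`.
#' }
#' By default only the congruent state vectors are tabulated (N+1 rows
#' of prefixes-of-ones; see [congruent_states()]). Sparse cells —
#' state vectors never observed at an age (table 1) or at all (table 2)
#' — get `NA` empirical values.
#'
#' @param panel A [build_panel()] result.
#' @param cohort A matching [simulate_cohort()] result.
#' @param states List of binary state vectors to tabulate; default the
#'   congruent ones.
#' @return List of two data frames, `state_given_age` (columns `state`,
#'   `age`, `predicted`, `empirical`, `n`) and `age_given_state`
#'   (columns `state`, `age`, `predicted`, `empirical`, `n_state`).
#' @export
compare_ci_vs_empirical <- function(panel, cohort,
                                    states = congruent_states(panel)) {
  stopifnot(inherits(panel, "biomarker_panel"),
            inherits(cohort, "biomarker_cohort"))
  key <- function(m) apply(m, 1L, paste, collapse = "")
  obs_key <- key(cohort$states)
  ages <- panel$age_grid
  n_at_age <- vapply(ages, function(a) sum(cohort$age == a), 0L)

  t1 <- do.call(rbind, lapply(states, function(sv) {
    lab <- paste(sv, collapse = "")
    pred <- state_vector_prob(panel, sv)
    emp <- vapply(seq_along(ages), function(i) {
      sel <- cohort$age == ages[i]
      if (!any(sel)) return(NA_real_)
      mean(obs_key[sel] == lab)
    }, 0)
    data.frame(state = lab, age = ages, predicted = as.numeric(pred),
               empirical = emp, n = n_at_age, stringsAsFactors = FALSE)
  }))

  t2 <- do.call(rbind, lapply(states, function(sv) {
    lab <- paste(sv, collapse = "")
    pred <- age_posterior(panel, sv)
    sel <- obs_key == lab
    n_state <- sum(sel)
    emp <- if (n_state == 0) rep(NA_real_, length(ages)) else {
      vapply(ages, function(a) mean(cohort$age[sel] == a), 0)
    }
    data.frame(state = lab, age = ages,
               predicted = as.numeric(pred[as.character(ages)]),
               empirical = emp, n_state = n_state,
               stringsAsFactors = FALSE)
  }))
  rownames(t1) <- rownames(t2) <- NULL
  list(state_given_age = t1, age_given_state = t2)
}
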