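#' Parameters of the oddball-search behavioral model
#'
#' The simulated subject searches for a color oddball among four
#' locations. Each trial is either an informed choice or a guess. The
#' probability of an informed choice is a logistic function of the
#' sensitivity for the current target color,
#' `p_I = 1 / (1 + exp(-(s(i_T) - offset)))`; informed choices are
#' correct with probability `informed_accuracy` (lapses go to a random
#' non-target location). Guesses pick a location with probability
#' proportional to its bias. After every trial the biases decay toward a
#' common floor and the current target location's bias is boosted:
#' `b <- bias_decay * b + bias_floor`, then
#' `b[j_T] <- b[j_T] + bias_increment`. The color sensitivities always
#' decay (`s <- sens_decay * s`), but the push apart —
#' `s[target color] + sens_reward`, `s[distracter color] - sens_penalty`
#' — happens *only after correct choices*, which couples color
#' sensitivity to outcome and is the designed source of the
#' color-by-outcome interaction in the sequential statistics.
#'
#' @param informed_accuracy Probability an informed choice is correct
#'   (default 0.95).
#' @param offset Logistic offset on the sensitivity scale (default 0.9).
#' @param bias_decay,bias_floor Multiplicative decay and additive floor
#'   of the location biases (defaults 0.5 and 0.1).
#' @param bias_increment Bias boost of the target location (default 1).
#' @param sens_decay Multiplicative decay of color sensitivities
#'   (default 0.4).
#' @param sens_reward,sens_penalty Post-correct sensitivity changes for
#'   the target and distracter colors (defaults +2 and 2).
#' @param n_locations,n_colors Task geometry (defaults 4 and 2).
#' @param init_sens,init_bias Initial state; the dynamics forget these
#'   within tens of trials (defaults all-zero sensitivities, unit
#'   biases).
#' @return An `oddball_params` list.
#' @export
oddball_params <- function(informed_accuracy = 0.95, offset = 0.9,
                           bias_decay = 0.5, bias_floor = 0.1,
                           bias_increment = 1, sens_decay = 0.4,
                           sens_reward = 2, sens_penalty = 2,
                           n_locations = 4L, n_colors = 2L,
                           init_sens = NULL, init_bias = NULL) {
  stopifnot(informed_accuracy >= 0, informed_accuracy <= 1,
            n_locations >= 2, n_colors >= 2,
            bias_floor > 0 || bias_decay > 0)
  if (is.null(init_sens)) init_sens <- rep(0, n_colors)
  if (is.null(init_bias)) init_bias <- rep(1, n_locations)
  stopifnot(length(init_sens) == n_colors,
            length(init_bias) == n_locations, all(init_bias >= 0))
  structure(
    list(informed_accuracy = informed_accuracy, offset = offset,
         bias_decay = bias_decay, bias_floor = bias_floor,
         bias_increment = bias_increment, sens_decay = sens_decay,
         sens_reward = sens_reward, sens_penalty = sens_penalty,
         n_locations = as.integer(n_locations),
         n_colors = as.integer(n_colors),
         init_sens = init_sens, init_bias = init_bias),
    class = "oddball_params"
  )
}

#' Simulate a session of the oddball search task
#'
#' Runs the model of [oddball_params()] for `n_trials` trials with
#' uniformly random target colors and locations, producing the choice
#' sequence and per-trial correctness. One guess-versus-informed coin,
#' one accuracy coin, one lapse draw and one guess draw are consumed per
#' trial, so a fixed seed yields a bit-identical session.
#'
#' @param n_trials Number of trials (the reference analyses use 1e5).
#' @param params An [oddball_params()] list.
#' @param seed Optional integer seed.
#' @return Data frame (one row per trial): `trial`, `target_color`,
#'   `target_location`, `choice`, `correct`.
#' @examples
#' head(simulate_session(100, seed = 1))
#' @export
simulate_session <- function(n_trials, params = oddball_params(),
                             seed = NULL) {
  stopifnot(inherits(params, "oddball_params"), n_trials >= 1)
  if (!is.null(seed)) set.seed(seed)
  n_loc <- params$n_locations
  n_col <- params$n_colors

  colors <- sample.int(n_col, n_trials, replace = TRUE)
  locations <- sample.int(n_loc, n_trials, replace = TRUE)
  u_informed <- stats::runif(n_trials)
  u_accurate <- stats::runif(n_trials)
  u_lapse <- stats::runif(n_trials)
  u_guess <- stats::runif(n_trials)

  s <- params$init_sens
  b <- params$init_bias
  choice <- integer(n_trials)
  correct <- logical(n_trials)

  for (t in seq_len(n_trials)) {
    i_t <- colors[t]
    j_t <- locations[t]
    p_informed <- 1 / (1 + exp(-(s[i_t] - params$offset)))
    if (u_informed[t] < p_informed) {
      if (u_accurate[t] < params$informed_accuracy) {
        choice[t] <- j_t
      } else {
        others <- seq_len(n_loc)[-j_t]
        choice[t] <- others[min(floor(u_lapse[t] * (n_loc - 1L)) + 1L,
                                n_loc - 1L)]
      }
    } else {
      tot <- sum(b)
      if (tot == 0) {
        choice[t] <- min(floor(u_guess[t] * n_loc) + 1L, n_loc)
      } else {
        choice[t] <- findInterval(u_guess[t] * tot, cumsum(b),
                                  left.open = TRUE) + 1L
      }
    }
    correct[t] <- choice[t] == j_t

    b <- params$bias_decay * b + params$bias_floor
    b[j_t] <- b[j_t] + params$bias_increment
    s <- params$sens_decay * s
    if (correct[t]) {
      s[i_t] <- s[i_t] + params$sens_reward
      s[-i_t] <- s[-i_t] - params$sens_penalty
    }
  }
  data.frame(trial = seq_len(n_trials), target_color = colors,
             target_location = locations, choice = choice,
             correct = correct)
}

#' Encode trial histories as same/different and correct/error labels
#'
#' Labels each trial (after the first `depth`) by the relation of the
#' preceding `depth` trials to the current one: target color same (`S`)
#' or different (`D`) from the current target color; target location
#' same (`S`) or different (`D`) from the current target location (all
#' three non-target locations count as different, repeated or not); and
#' outcome correct (`C`) or error (`E`). Label strings read
#' most-recent-first: in `"SD"`, `S` is the immediately preceding trial.
#'
#' @param trials A [simulate_session()] data frame.
#' @param depth History depth H (>= 1; the first H trials are dropped).
#' @return Data frame with columns `trial`, `color`, `location`,
#'   `outcome`, `correct` (correctness of the *current* trial).
#' @export
encode_histories <- function(trials, depth = 1L) {
  stopifnot(depth >= 1L, nrow(trials) > depth)
  n <- nrow(trials)
  idx <- (depth + 1L):n
  lab <- function(values, current, yes, no) {
    # matrix of lag-k comparisons, most recent lag first
    m <- vapply(seq_len(depth), function(k) {
      ifelse(values[idx - k] == current[idx], yes, no)
    }, character(length(idx)))
    if (length(idx) == 1L) m <- matrix(m, nrow = 1L)
    apply(m, 1L, paste, collapse = "")
  }
  outcome_m <- vapply(seq_len(depth), function(k) {
    ifelse(trials$correct[idx - k], "C", "E")
  }, character(length(idx)))
  if (length(idx) == 1L) outcome_m <- matrix(outcome_m, nrow = 1L)
  data.frame(
    trial = idx,
    color = lab(trials$target_color, trials$target_color, "S", "D"),
    location = lab(trials$target_location, trials$target_location,
                   "S", "D"),
    outcome = apply(outcome_m, 1L, paste, collapse = ""),
    correct = trials$correct[idx],
    stringsAsFactors = FALSE
  )
}

clopper_pearson <- function(k, n, level = 0.95) {
  a <- (1 - level) / 2
  lower <- if (k == 0) 0 else stats::qbeta(a, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - a, k + 1, n - k)
  c(lower, upper)
}

#' Accuracy conditioned on one selection-history variable
#'
#' Fraction of correct choices among trials sharing each history label
#' (e.g. color history `"SS"`), with exact Clopper-Pearson binomial
#' confidence intervals. Empty label bins are dropped.
#'
#' @param trials A [simulate_session()] data frame.
#' @param variable One of `"color"`, `"location"`, `"outcome"`.
#' @param depth History depth.
#' @param level Confidence level (default 0.95).
#' @return Data frame with columns `label`, `n`, `k`, `frac`, `lower`,
#'   `upper`, sorted by label.
#' @export
history_accuracy <- function(trials, variable = c("color", "location",
                                                  "outcome"),
                             depth = 1L, level = 0.95) {
  variable <- match.arg(variable)
  h <- encode_histories(trials, depth)
  labels <- sort(unique(h[[variable]]))
  rows <- lapply(labels, function(lb) {
    sel <- h[[variable]] == lb
    n <- sum(sel); k <- sum(h$correct[sel])
    ci <- clopper_pearson(k, n, level)
    data.frame(label = lb, n = n, k = k, frac = k / n,
               lower = ci[1], upper = ci[2], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Joint-history benchmark against conditional independence
#'
#' For every pairwise combination of two history variables (e.g. color
#' history x outcome history at a given depth), compares the measured
#' probability of a correct choice given the joint history with the
#' probability predicted by the two-source combination rule from the two
#' marginal history accuracies and the overall fraction correct (the
#' prior). Points whose Clopper-Pearson 95% interval spans more than
#' `max_ci_span` are flagged as poorly estimated and excluded from the
#' summary regression of predicted on measured; a slope near 1 with the
#' cloud on the diagonal indicates the two history variables influence
#' performance independently.
#'
#' @param trials A [simulate_session()] data frame.
#' @param var1,var2 Two distinct history variables among `"color"`,
#'   `"location"`, `"outcome"`.
#' @param depth History depth (1-4 is practical; 4^depth joint labels
#'   must be populated).
#' @param max_ci_span Exclusion threshold on the 95% CI span
#'   (default 0.15).
#' @return List with `table` (columns `label1`, `label2`, `n`, `k`,
#'   `measured`, `lower`, `upper`, `predicted`, `wide_ci`), `prior`
#'   (overall fraction correct among labeled trials), `slope`,
#'   `slope_ci` (95% CI; both `NA` with a note when fewer than 3
#'   well-estimated points).
#' @export
joint_history_comparison <- function(trials, var1, var2, depth = 1L,
                                     max_ci_span = 0.15) {
  vars <- c("color", "location", "outcome")
  stopifnot(var1 %in% vars, var2 %in% vars, var1 != var2)
  h <- encode_histories(trials, depth)
  prior_k <- sum(h$correct); prior_n <- nrow(h)
  prior <- prior_k / prior_n
  pv_prior <- prob_vector(c("1" = prior, "0" = 1 - prior))

  acc <- function(v) {
    tab <- history_accuracy(trials, v, depth)
    stats::setNames(tab$frac, tab$label)
  }
  acc1 <- acc(var1); acc2 <- acc(var2)

  joint <- paste(h[[var1]], h[[var2]], sep = "\r")
  labels <- sort(unique(joint))
  rows <- lapply(labels, function(lb) {
    parts <- strsplit(lb, "\r", fixed = TRUE)[[1L]]
    sel <- joint == lb
    n <- sum(sel); k <- sum(h$correct[sel])
    ci <- clopper_pearson(k, n)
    p1 <- acc1[[parts[1L]]]; p2 <- acc2[[parts[2L]]]
    pred <- combine_two(prob_vector(c("1" = p1, "0" = 1 - p1)),
                        prob_vector(c("1" = p2, "0" = 1 - p2)),
                        pv_prior)$posterior[["1"]]
    data.frame(label1 = parts[1L], label2 = parts[2L], n = n, k = k,
               measured = k / n, lower = ci[1], upper = ci[2],
               predicted = pred, wide_ci = (ci[2] - ci[1]) > max_ci_span,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL

  good <- tab[!tab$wide_ci, , drop = FALSE]
  slope <- NA_real_; slope_ci <- c(NA_real_, NA_real_); note <- NULL
  if (nrow(good) >= 3L && stats::sd(good$measured) > 0) {
    fit <- stats::lm(predicted ~ measured, data = good)
    slope <- unname(stats::coef(fit)[2L])
    slope_ci <- unname(stats::confint(fit)["measured", ])
  } else {
    note <- "fewer than 3 well-estimated points: regression skipped"
  }
  list(table = tab, prior = prior, slope = slope, slope_ci = slope_ci,
       note = note)
}
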