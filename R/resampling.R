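#' An observed binomial proportion
#'
#' Records a measured probability together with the number of
#' observations behind it, which is what the resampling machinery needs
#' to propagate sampling uncertainty through a combination formula.
#'
#' @param successes Nonnegative integer count of successes.
#' @param trials Positive integer number of trials (`successes <= trials`).
#' @return An `observed_proportion` with fields `successes`, `trials`,
#'   `estimate = successes/trials`.
#' @export
observed_proportion <- function(successes, trials) {
  stopifnot(length(successes) == 1L, length(trials) == 1L,
            trials >= 1, successes >= 0, successes <= trials,
            successes == round(successes), trials == round(trials))
  structure(list(successes = as.integer(successes),
                 trials = as.integer(trials),
                 estimate = successes / trials),
            class = "observed_proportion")
}

#' @export
print.observed_proportion <- function(x, ...) {
  cat(sprintf("<observed_proportion %d/%d = %.4f>\n",
              x$successes, x$trials, x$estimate))
  invisible(x)
}

# Built-in vectorized combiners. Each takes a matrix of proportions
# (rows = bootstrap draws, columns = inputs in their documented order)
# and returns one combined value per row. Invalid rows come back NaN/NA.
builtin_combiners <- list(
  # columns: P(C=1|A), P(C=1|B), prior P(C=1)
  two_binary = function(p) {
    pa <- p[, 1L]; pb <- p[, 2L]; pr <- p[, 3L]
    f1 <- ifelse(pr == 0, NaN, pa * pb / pr)
    f0 <- ifelse(pr == 1, NaN, (1 - pa) * (1 - pb) / (1 - pr))
    out <- f1 / (f1 + f0)
    out[is.finite(f1 + f0) & (f1 + f0) == 0] <- NaN
    out
  },
  # columns: p_A alone, p_V alone, chance
  exclusive = function(p) {
    pa <- p[, 1L]; pv <- p[, 2L]; ch <- p[, 3L]
    bad <- ch <= 0 | ch >= 1
    num <- pa * pv
    den <- num + (1 - pa) * (1 - pv) * ch / (1 - ch)
    out <- num / den
    out[bad | den == 0] <- NaN
    out
  }
)

#' Resampled confidence interval for a combined probability
#'
#' Propagates binomial sampling uncertainty through a combination
#' formula. Each input probability is backed by its observation count;
#' every bootstrap draw resamples each count as
#' `k* ~ Binomial(trials, estimate)`, forms `p* = k*/trials`, applies the
#' combiner, and the central `level` percentile range of the resampled
#' combined values is the interval. The point estimate is the plug-in
#' combiner value at the observed proportions (never resampled).
#'
#' Resamples on which the combiner is degenerate (e.g. a resampled 0 or 1
#' lands in a denominator) are redrawn up to `max_retries` times; any
#' still-degenerate draws have their proportions clamped to
#' `[1/(2n), 1 - 1/(2n)]` and the result carries a `n_clamped` flag.
#'
#' @param inputs List of [observed_proportion()]s, in the argument order
#'   the combiner expects.
#' @param combiner Either the name of a built-in vectorized combiner —
#'   `"two_binary"` (`P(C=1|A)`, `P(C=1|B)`, prior) or `"exclusive"`
#'   (`p_A`, `p_V`, chance) — or a function taking a numeric vector of
#'   proportions (one per input) and returning a single value.
#' @param n_boot Number of bootstrap draws (at least 100; default 10000).
#' @param level Confidence level in (0, 1), e.g. `0.68` or `0.95`.
#' @param seed Optional integer seed for reproducibility.
#' @param max_retries Redraw budget for degenerate resamples.
#' @return A `resampled_interval`: list with `point`, `lower`, `upper`,
#'   `level`, `n_boot`, `seed`, `n_clamped`, and the resampled `draws`.
#' @examples
#' resample_combined(
#'   list(observed_proportion(60, 100), observed_proportion(60, 100),
#'        observed_proportion(40, 100)),
#'   combiner = "two_binary", n_boot = 1000, level = 0.95, seed = 1
#' )
#' @export
resample_combined <- function(inputs, combiner, n_boot = 10000,
                              level = 0.95, seed = NULL,
                              max_retries = 100) {
  stopifnot(is.list(inputs), length(inputs) >= 1L,
            all(vapply(inputs, inherits, TRUE, "observed_proportion")),
            n_boot >= 100, level > 0, level < 1)
  if (!is.null(seed)) set.seed(seed)

  est <- vapply(inputs, `[[`, 0, "estimate")
  tr <- vapply(inputs, `[[`, 0L, "trials")

  fn <- if (is.character(combiner)) {
    f <- builtin_combiners[[match.arg(combiner, names(builtin_combiners))]]
    f
  } else if (is.function(combiner)) {
    function(p) apply(p, 1L, combiner)
  } else stop("`combiner` must be a function or a built-in name")

  draw_p <- function(n) {
    vapply(seq_along(inputs),
           function(i) stats::rbinom(n, tr[i], est[i]) / tr[i],
           numeric(n))
  }

  p <- draw_p(n_boot)
  if (n_boot == 1L) p <- matrix(p, nrow = 1L)
  vals <- fn(p)
  n_clamped <- 0L
  for (attempt in seq_len(max_retries)) {
    bad <- which(!is.finite(vals))
    if (!length(bad)) break
    p_new <- draw_p(length(bad))
    if (length(bad) == 1L) p_new <- matrix(p_new, nrow = 1L)
    p[bad, ] <- p_new
    vals[bad] <- fn(p[bad, , drop = FALSE])
  }
  bad <- which(!is.finite(vals))
  if (length(bad)) {
    n_clamped <- length(bad)
    lo <- 1 / (2 * tr); hi <- 1 - 1 / (2 * tr)
    p[bad, ] <- pmin(pmax(p[bad, , drop = FALSE],
                          matrix(lo, length(bad), length(tr), byrow = TRUE)),
                     matrix(hi, length(bad), length(tr), byrow = TRUE))
    vals[bad] <- fn(p[bad, , drop = FALSE])
  }

  point <- fn(matrix(est, nrow = 1L))
  qs <- stats::quantile(vals, probs = c((1 - level) / 2, (1 + level) / 2),
                        names = FALSE)
  structure(
    list(point = point, lower = qs[1L], upper = qs[2L], level = level,
         n_boot = as.integer(n_boot), seed = seed,
         n_clamped = n_clamped, draws = vals),
    class = "resampled_interval"
  )
}

#' @export
print.resampled_interval <- function(x, ...) {
  cat(sprintf("<resampled_interval> %.4f [%.4f, %.4f] (%d%%, %d draws%s)\n",
              x$point, x$lower, x$upper, round(100 * x$level), x$n_boot,
              if (x$n_clamped > 0) sprintf(", %d clamped", x$n_clamped)
              else ""))
  invisible(x)
}
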