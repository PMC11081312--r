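#' Predict multisensory performance from unisensory performance
#'
#' For each visual performance level (e.g. one per stimulus luminance),
#' predicts the proportion correct expected when the auditory and visual
#' cues are presented together and act on the choice in a conditionally
#' independent way. The prediction uses the exclusive-condition
#' combination rule [combine_exclusive()] — the unisensory proportions
#' enter directly and the chance level of the task plays the role of the
#' prior. Sampling uncertainty from the finite unisensory trial counts is
#' propagated with [resample_combined()], yielding a confidence ribbon.
#'
#' Visual performance below chance is allowed (it can happen by sampling
#' noise) but flagged with a warning. Chance itself is a design constant
#' of the task and is not resampled.
#'
#' @param p_aud Proportion correct in the unisensory auditory condition.
#' @param p_vis_curve Vector of proportions correct in the unisensory
#'   visual condition, one per stimulus level.
#' @param chance Chance performance of the task (default 0.5, the
#'   two-alternative case).
#' @param n_aud_trials,n_vis_trials Trial counts behind the auditory
#'   value and behind each visual value (defaults 2000 and 500).
#' @param level Confidence level for the ribbon (default 0.68).
#' @param n_boot Bootstrap draws per point (default 2000).
#' @param seed Optional integer seed.
#' @return Data frame with one row per visual level: `p_vis`,
#'   `predicted`, `lower`, `upper`.
#' @examples
#' predict_multisensory(0.75, c(0.5, 0.75, 0.95), seed = 1)
#' @export
predict_multisensory <- function(p_aud, p_vis_curve, chance = 0.5,
                                 n_aud_trials = 2000, n_vis_trials = 500,
                                 level = 0.68, n_boot = 2000,
                                 seed = NULL) {
  stopifnot(chance > 0, chance < 1, p_aud >= 0, p_aud <= 1,
            all(p_vis_curve >= 0 & p_vis_curve <= 1))
  if (any(p_vis_curve < chance)) {
    warning("visual performance below chance at ",
            sum(p_vis_curve < chance), " level(s)")
  }
  if (!is.null(seed)) set.seed(seed)
  aud <- observed_proportion(round(p_aud * n_aud_trials), n_aud_trials)
  rows <- lapply(p_vis_curve, function(pv) {
    vis <- observed_proportion(round(pv * n_vis_trials), n_vis_trials)
    # chance is exact: represent it with an effectively infinite count
    ch <- observed_proportion(round(chance * 1e9), 1e9)
    ri <- resample_combined(list(aud, vis, ch), combiner = "exclusive",
                            n_boot = n_boot, level = level)
    data.frame(p_vis = pv,
               predicted = combine_exclusive(aud$estimate, vis$estimate,
                                             chance),
               lower = ri$lower, upper = ri$upper)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Synthetic unisensory psychometric curve
#'
#' Logistic-in-log-luminance performance curve running from chance at
#' zero stimulus strength to ~1 at high strength; a plumbing helper for
#' end-to-end demonstrations, not a fit to any data. At
#' `luminance == threshold` the curve is halfway between chance and 1.
#'
#' @param luminance Vector of nonnegative stimulus strengths.
#' @param slope Logistic slope in log-luminance units.
#' @param threshold Luminance at the half-way point.
#' @param chance Lower asymptote (chance performance).
#' @return Vector of proportions correct, monotone in `luminance`.
#' @export
synth_psychometric <- function(luminance, slope = 2, threshold = 1,
                               chance = 0.5) {
  stopifnot(chance > 0, chance < 1, threshold > 0, slope > 0,
            all(luminance >= 0))
  p <- ifelse(luminance == 0, 0,
              stats::plogis(slope * (log(luminance) - log(threshold))))
  chance + (1 - chance) * p
}
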