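#' N-way joint count table over named discrete variables
#'
#' The canonical data structure for measured three-way (or N-way)
#' relationships: a nonnegative-integer count array with one dimension per
#' variable and one cell per combination of states. Counts, not
#' probabilities, are canonical — resampling uncertainties require the
#' raw numbers of observations, and frequency trees are counts.
#'
#' @param counts Integer array (or vector coercible to one) with complete
#'   `dimnames`: one dimension per variable, named, with state labels.
#' @return A `joint_count_table` object.
#' @examples
#' carol_tree()
#' @export
joint_count_table <- function(counts) {
  if (is.null(dim(counts))) stop("`counts` must be an array with dimnames")
  dn <- dimnames(counts)
  if (is.null(dn) || is.null(names(dn)) || any(!nzchar(names(dn)))) {
    stop("`counts` must have named dimnames (variable names + state labels)")
  }
  if (anyDuplicated(names(dn))) stop("variable names must be unique")
  for (v in names(dn)) {
    if (anyDuplicated(dn[[v]])) {
      stop("state labels for variable ", v, " must be unique")
    }
  }
  if (anyNA(counts) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-9)) {
    stop("counts must be nonnegative integers")
  }
  counts <- round(counts)
  if (sum(counts) < 1) stop("total count must be at least 1")
  structure(list(counts = counts, variables = dn),
            class = "joint_count_table")
}

#' @export
print.joint_count_table <- function(x, ...) {
  cat("<joint_count_table: ",
      paste(names(x$variables), vapply(x$variables, length, 1L),
            sep = "(", collapse = ") x "),
      "), total count ", sum(x$counts), ">\n", sep = "")
  print(x$counts, ...)
  invisible(x)
}

# probability array P(all variables) from counts
joint_probs <- function(table) table$counts / sum(table$counts)

# marginalize a probability (or count) array onto the given variables,
# preserving their order as in `vars`
marginalize <- function(arr, vars) {
  keep <- match(vars, names(dimnames(arr)))
  if (anyNA(keep)) stop("unknown variable(s): ",
                        paste(vars[is.na(keep)], collapse = ", "))
  apply(arr, keep, sum)
}

check_vars <- function(table, ...) {
  vars <- c(...)
  missing <- setdiff(vars, names(table$variables))
  if (length(missing)) {
    stop("variable(s) not in table: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(vars)) stop("variables must be distinct")
  invisible(vars)
}

#' Conditional (or marginal) distribution from a count table
#'
#' Computes `P(target | given)` directly from counts: the counts of the
#' target's states within the conditioning slice, divided by the slice
#' total. With an empty `given` this is the marginal distribution of
#' `target`.
#'
#' @param table A [joint_count_table()].
#' @param target Name of the variable whose distribution is wanted.
#' @param given Named list/vector of conditioning assignments, e.g.
#'   `list(A = "1")`. May be empty.
#' @return A [prob_vector()] over the target's states.
#' @examples
#' conditional(carol_tree(), "C", list(A = "0"))  # P(C|A=0): 0.8 / 0.2
#' @export
conditional <- function(table, target, given = list()) {
  stopifnot(inherits(table, "joint_count_table"))
  given <- as.list(given)
  check_vars(table, target, names(given))
  arr <- table$counts
  dn <- dimnames(arr)
  idx <- lapply(names(dn), function(v) {
    if (v %in% names(given)) {
      i <- match(as.character(given[[v]]), dn[[v]])
      if (is.na(i)) stop("unknown state ", given[[v]], " for variable ", v)
      i
    } else seq_along(dn[[v]])
  })
  slice <- do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
  tgt_counts <- marginalize(slice, target)
  if (sum(tgt_counts) == 0) {
    stop("zero conditioning mass: no observations with ",
         paste(names(given), unlist(given), sep = "=", collapse = ", "))
  }
  prob_vector(tgt_counts / sum(tgt_counts))
}

#' Joint probability of a full or partial state assignment
#'
#' @param table A [joint_count_table()].
#' @param assignment Named list/vector of variable = state.
#' @return The empirical probability of the assignment.
#' @export
joint_prob <- function(table, assignment) {
  stopifnot(inherits(table, "joint_count_table"))
  assignment <- as.list(assignment)
  check_vars(table, names(assignment))
  p <- joint_probs(table)
  dn <- dimnames(p)
  idx <- lapply(names(dn), function(v) {
    if (v %in% names(assignment)) {
      match(as.character(assignment[[v]]), dn[[v]])
    } else seq_along(dn[[v]])
  })
  sum(do.call(`[`, c(list(p), idx, list(drop = FALSE))))
}

#' Test conditional independence of two variables given a third
#'
#' Measures, cell by cell, how far a count table deviates from
#' `P(A,B|C) = P(A|C) P(B|C)`. The report contains the per-cell
#' residuals, their maximum absolute value, the g-factor diagnostic
#' (see [g_factor()]), and a pass flag at the chosen tolerance. This is a
#' numerical diagnostic for exact or near-exact tables; it is not a
#' hypothesis test and produces no p-value.
#'
#' @param table A [joint_count_table()].
#' @param a,b Names of the two evidence variables.
#' @param c Name of the conditioning (outcome) variable.
#' @param tol Pass/fail tolerance on the maximum absolute residual
#'   (default `1e-9`, appropriate for exactly constructed tables).
#' @return A `ci_report`: list with `max_abs_deviation`, `deviations`
#'   (array over A, B, C states; NA where `P(C=c) = 0`), `g_values`,
#'   `passes`, `tol`.
#' @examples
#' check_conditional_independence(carol_tree(), "A", "B", "C")
#' @export
check_conditional_independence <- function(table, a, b, c, tol = 1e-9) {
  check_vars(table, a, b, c)
  for (v in c(a, b, c)) {
    if (length(table$variables[[v]]) < 2L) {
      stop("variable ", v, " is degenerate (single state)")
    }
  }
  p <- marginalize(joint_probs(table), c(a, b, c))
  p_c <- marginalize(p, c)
  dev <- array(NA_real_, dim = dim(p), dimnames = dimnames(p))
  for (k in seq_along(p_c)) {
    if (p_c[k] == 0) next
    p_ab_c <- p[, , k] / p_c[k]
    p_a_c <- rowSums(p[, , k, drop = FALSE]) / p_c[k]
    p_b_c <- colSums(p[, , k]) / p_c[k]
    dev[, , k] <- p_ab_c - outer(p_a_c, p_b_c)
  }
  max_dev <- max(abs(dev), na.rm = TRUE)
  structure(
    list(max_abs_deviation = max_dev,
         deviations = dev,
         g_values = g_factor(table, a, b, c),
         passes = max_dev <= tol,
         tol = tol),
    class = "ci_report"
  )
}

#' @export
print.ci_report <- function(x, ...) {
  cat("<ci_report> max |P(A,B|C) - P(A|C)P(B|C)| =",
      format(x$max_abs_deviation), "->",
      if (x$passes) "PASS" else "FAIL",
      sprintf("(tol %g)\n", x$tol))
  invisible(x)
}

#' g-factor diagnostic for conditional independence
#'
#' For each (A, B) cell,
#' \deqn{g(A,B) = \frac{P(A,B)}{\sum_c P(A|c)\,P(B|c)\,P(c)}.}
#' When A and B are conditionally independent given C, every g equals 1;
#' conversely (provided the identifiability condition
#' [identifiability_condition()] holds) an all-ones g implies conditional
#' independence. Cells whose denominator is zero are returned as `NA`.
#'
#' @inheritParams check_conditional_independence
#' @return Numeric matrix over (A, B) states.
#' @export
g_factor <- function(table, a, b, c) {
  check_vars(table, a, b, c)
  p <- marginalize(joint_probs(table), c(a, b, c))
  p_ab <- marginalize(p, c(a, b))
  p_c <- marginalize(p, c)
  denom <- matrix(0, nrow = dim(p)[1L], ncol = dim(p)[2L],
                  dimnames = dimnames(p)[1:2])
  for (k in seq_along(p_c)) {
    if (p_c[k] == 0) next
    p_a_c <- rowSums(p[, , k, drop = FALSE]) / p_c[k]
    p_b_c <- colSums(p[, , k]) / p_c[k]
    denom <- denom + outer(p_a_c, p_b_c) * p_c[k]
  }
  g <- p_ab / denom
  g[denom == 0] <- NA_real_
  if (anyNA(g)) {
    warning("g-factor undefined (zero denominator) in ",
            sum(is.na(g)), " cell(s)")
  }
  g
}

#' Identifiability condition for inferring independence from predictability
#'
#' Predictability of C from A and B via the combination rule implies
#' conditional independence only when the outcome variable has enough
#' states: `N_C >= min(N_A, N_B)`. Below that, the defining linear system
#' is underdetermined and non-independent tables can mimic predictability.
#'
#' @param n_a,n_b,n_c Numbers of states of A, B and the outcome C
#'   (each at least 2).
#' @return `TRUE` if the condition holds.
#' @examples
#' identifiability_condition(2, 2, 2)  # TRUE
#' identifiability_condition(4, 4, 2)  # FALSE
#' @export
identifiability_condition <- function(n_a, n_b, n_c) {
  stopifnot(n_a >= 2, n_b >= 2, n_c >= 2)
  n_c >= min(n_a, n_b)
}

#' Measured versus predicted outcome posteriors, cell by cell
#'
#' For every evidence combination (a_i, b_j) with observations, compares
#' the outcome posterior measured directly from the table,
#' `P(C | a_i, b_j)`, with the posterior predicted by the two-source
#' combination rule from `P(C|a_i)`, `P(C|b_j)` and the marginal `P(C)`.
#' When A and B are conditionally independent given C the two columns are
#' identical, so a scatter of measured against predicted falls on the
#' diagonal; systematic departures quantify the violation.
#'
#' @inheritParams check_conditional_independence
#' @return Data frame with columns `a`, `b`, `c_state`, `n` (count in the
#'   (a, b) slice), `measured`, `predicted`. Evidence cells with zero mass
#'   are skipped with a warning.
#' @export
predicted_vs_measured <- function(table, a, b, c) {
  check_vars(table, a, b, c)
  a_states <- table$variables[[a]]
  b_states <- table$variables[[b]]
  prior <- conditional(table, c)
  rows <- list(); skipped <- 0L
  for (ai in a_states) for (bj in b_states) {
    giv <- stats::setNames(list(ai, bj), c(a, b))
    cnt <- marginalize(table$counts, c(a, b))[ai, bj]
    if (cnt == 0) { skipped <- skipped + 1L; next }
    measured <- conditional(table, c, giv)
    predicted <- combine_two(
      conditional(table, c, stats::setNames(list(ai), a)),
      conditional(table, c, stats::setNames(list(bj), b)),
      prior
    )$posterior
    rows[[length(rows) + 1L]] <- data.frame(
      a = ai, b = bj, c_state = names(prior), n = cnt,
      measured = as.numeric(measured[names(prior)]),
      predicted = as.numeric(predicted[names(prior)]),
      stringsAsFactors = FALSE
    )
  }
  if (skipped > 0L) {
    warning(skipped, " evidence cell(s) with zero mass skipped")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' The barking-dog frequency tree
#'
#' The canonical 2x2x2 worked example: A = "time is after 6 pm",
#' C = "Carol is home", B = "the dog is barking", over 100 observations
#' constructed so that A and B are conditionally independent given C.
#' Before/after 6 pm are equally likely; Carol is home with probability
#' 0.6 after 6 pm and 0.2 before; the dog barks with probability 0.1 when
#' she is home and 0.6 when she is away.
#'
#' @return A [joint_count_table()] over variables A, B, C with states
#'   "0"/"1" and total count 100.
#' @examples
#' joint_prob(carol_tree(), list(A = "1", B = "1", C = "1"))  # 3/100
#' @export
carol_tree <- function() {
  counts <- array(
    0L, dim = c(2L, 2L, 2L),
    dimnames = list(A = c("0", "1"), B = c("0", "1"), C = c("0", "1"))
  )
  counts["1", "1", "1"] <- 3L;  counts["1", "0", "1"] <- 27L
  counts["1", "1", "0"] <- 12L; counts["1", "0", "0"] <- 8L
  counts["0", "1", "1"] <- 1L;  counts["0", "0", "1"] <- 9L
  counts["0", "1", "0"] <- 24L; counts["0", "0", "0"] <- 16L
  joint_count_table(counts)
}
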