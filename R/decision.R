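round_half_away <- function(x) {
  trunc(x + 0.5 * sign(x))
}

#' Expected decision from an activation distribution
#'
#' Collapses a probability distribution over rank-sorted output nodes to one
#' integer rank: the probability-weighted mean rank (tactile score times node
#' activation level), rounded half away from zero.
#'
#' @param activation Probability vector over ranks 1..M, or a matrix with one
#'   distribution per row.
#' @param ranks Rank values of the nodes (default `1..M`).
#' @return Integer decision(s) in `[1, M]`.
#' @export
#' @examples
#' expected_decision(c(0, 0, 0, 0, 1)) # one-hot at 5
#' expected_decision(rep(1 / 42, 42)) # uniform: round(21.5) = 22
expected_decision <- function(activation, ranks = NULL) {
  if (is.matrix(activation)) {
    return(unname(apply(activation, 1, expected_decision, ranks = ranks)))
  }
  check_prob(activation, "activation")
  ranks <- ranks %||% seq_along(activation)
  as.integer(round_half_away(sum(ranks * activation)))
}

check_decisions <- function(decisions, reference_means) {
  if (!all(c("material_id", "decision") %in% names(decisions))) {
    abort_invalid("`decisions` needs columns material_id and decision")
  }
  if (!all(c("material_id", "ref_mean") %in% names(reference_means))) {
    abort_invalid("`reference_means` needs columns material_id and ref_mean")
  }
  miss <- setdiff(unique(decisions$material_id), reference_means$material_id)
  if (length(miss) > 0) {
    abort_invalid(sprintf("no reference mean for material(s) %s", toString(miss)))
  }
}

#' Tolerance-bounded classification accuracy
#'
#' A decision counts as correct when it lies within `tolerance` ranks of the
#' reference mean human decision for its material (distance less than or
#' equal to the tolerance). The reference means stay real-valued; only the
#' decision is an integer.
#'
#' @param decisions Tibble with columns `material_id`, `decision` (one row
#'   per evaluated trial).
#' @param reference_means Tibble with columns `material_id`, `ref_mean`.
#' @param tolerance Allowed rank distance, >= 0.
#' @return Fraction of correct decisions in `[0, 1]`.
#' @export
tolerance_accuracy <- function(decisions, reference_means, tolerance = 2) {
  check_number(tolerance, "tolerance", min = 0)
  check_decisions(decisions, reference_means)
  d <- dplyr::inner_join(decisions, reference_means, by = "material_id")
  mean(abs(d$decision - d$ref_mean) <= tolerance)
}

#' Decision error at a tolerance level
#'
#' The complement of [tolerance_accuracy()]: the fraction of evaluated
#' trials whose expected decision deviates from the reference mean by more
#' than the tolerance.
#'
#' @inheritParams tolerance_accuracy
#' @return Fraction of incorrect decisions in `[0, 1]`.
#' @export
decision_error <- function(decisions, reference_means, tolerance = 2) {
  1 - tolerance_accuracy(decisions, reference_means, tolerance)
}

#' Accuracy as a function of tolerance level
#'
#' Evaluates [tolerance_accuracy()] over a grid of tolerance levels. The
#' curve is nondecreasing and reaches 1 at tolerance M - 1.
#'
#' @inheritParams tolerance_accuracy
#' @param tolerances Ascending tolerance levels (default 0..41).
#' @return A tibble (class `accuracy_curve`) with columns `tolerance`,
#'   `accuracy`.
#' @export
accuracy_curve <- function(decisions, reference_means, tolerances = 0:41) {
  if (is.unsorted(tolerances)) abort_invalid("`tolerances` must be ascending")
  acc <- purrr::map_dbl(tolerances, function(t) {
    tolerance_accuracy(decisions, reference_means, t)
  })
  structure(
    tibble::tibble(tolerance = tolerances, accuracy = acc),
    class = c("accuracy_curve", "tbl_df", "tbl", "data.frame")
  )
}

#' Horizontal gap between two accuracy curves
#'
#' The tolerance difference needed for the second (weaker) system to reach
#' the accuracy at which the first saturates, linearly interpolating between
#' tolerance levels; optionally expressed as a percentage of the material
#' scale (a 4-rank gap on a 42-material scale is 9.5%).
#'
#' @param curve_a,curve_b Accuracy curves from [accuracy_curve()]; `curve_a`
#'   is the stronger reference (e.g. human), `curve_b` the comparison.
#' @param level Accuracy level at which to measure; defaults to where
#'   `curve_a` saturates (its maximum accuracy).
#' @return A list with `gap` (rank units) and `gap_pct` (percent of the
#'   material scale, using `max(tolerance) + 1` materials).
#' @export
#' @examples
#' tolerance_gap_pct(4, 42)
curve_gap <- function(curve_a, curve_b, level = NULL) {
  level <- level %||% max(curve_a$accuracy)
  t_at <- function(curve) {
    i <- which(curve$accuracy >= level - 1e-12)[1]
    if (is.na(i)) return(max(curve$tolerance))
    if (i == 1) return(curve$tolerance[1])
    # linear interpolation between the bracketing tolerance levels
    a0 <- curve$accuracy[i - 1]; a1 <- curve$accuracy[i]
    t0 <- curve$tolerance[i - 1]; t1 <- curve$tolerance[i]
    if (a1 == a0) t1 else t0 + (level - a0) / (a1 - a0) * (t1 - t0)
  }
  gap <- t_at(curve_b) - t_at(curve_a)
  n_mat <- max(curve_a$tolerance) + 1
  list(gap = gap, gap_pct = tolerance_gap_pct(gap, n_mat))
}

#' Express a tolerance gap as a percentage of the material scale
#'
#' @param gap Tolerance gap in rank units.
#' @param n_materials Number of materials on the scale (default 42).
#' @return Percentage (0-100).
#' @export
#' @examples
#' round(tolerance_gap_pct(4, 42), 1) # 9.5
tolerance_gap_pct <- function(gap, n_materials = 42) {
  100 * gap / n_materials
}
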