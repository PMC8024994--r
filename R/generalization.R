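#' Decompose a histogram as a convex combination of basis histograms
#'
#' Finds the weights w (w >= 0, sum w = 1) minimizing the root-mean-square
#' deviation between the target histogram and the weighted combination of
#' basis histograms. Used to quantify how well an untrained material's
#' decision histogram is explained by the trained materials' histograms:
#' middle-ranked materials, whose histograms overlap their neighbours',
#' decompose with small RMSE, while the relatively unique side materials fit
#' poorly.
#'
#' The simplex constraint keeps the combination a histogram. Solved with an
#' active-set method (Lawson-Hanson style, with the sum-to-one equality
#' handled through its KKT system); `constrain = FALSE` gives the
#' unconstrained least-squares variant for sensitivity analysis (its
#' combination need not be a histogram).
#'
#' @param target Probability vector over ranks (length M).
#' @param basis Matrix with one basis histogram per row (K x M), or a list of
#'   probability vectors.
#' @param constrain Keep the simplex constraint (default `TRUE`).
#' @return A list of class `histogram_decomposition`: `weights` (length K),
#'   `rmse`, `fitted` (length M).
#' @export
#' @examples
#' b <- rbind(c(1, 0, 0), c(0, 0, 1))
#' fit_linear_combination(c(0.5, 0, 0.5), b)$weights
fit_linear_combination <- function(target, basis, constrain = TRUE) {
  if (is.list(basis) && !is.data.frame(basis)) basis <- do.call(rbind, basis)
  basis <- as.matrix(basis)
  check_prob(target, "target")
  if (ncol(basis) != length(target)) {
    abort_invalid("basis histograms and target are over different rank supports")
  }
  a <- t(basis) # M x K, columns are basis histograms
  if (constrain) {
    w <- simplex_ls(a, target)
  } else {
    w <- qr.solve(crossprod(a) + 1e-12 * diag(ncol(a)), crossprod(a, target))
    w <- drop(w)
  }
  fitted <- drop(a %*% w)
  structure(
    list(
      weights = unname(w), rmse = sqrt(mean((fitted - target)^2)),
      fitted = fitted, constrained = constrain
    ),
    class = "histogram_decomposition"
  )
}

# least squares of ||a w - b|| over the probability simplex (w >= 0, sum 1).
# Active-set iteration: solve the equality-constrained KKT system on the
# current support, drop negative weights, and re-admit coordinates whose
# reduced gradient is negative until the KKT conditions hold.
simplex_ls <- function(a, b, tol = 1e-10, max_iter = NULL) {
  k <- ncol(a)
  if (k == 1L) return(1)
  g_full <- crossprod(a) # K x K
  h_full <- drop(crossprod(a, b))
  max_iter <- max_iter %||% (10L * k)
  support <- seq_len(k)
  kkt_solve <- function(s) {
    ns <- length(s)
    m <- rbind(
      cbind(2 * g_full[s, s, drop = FALSE] + 1e-12 * diag(ns), rep(1, ns)),
      c(rep(1, ns), 0)
    )
    sol <- solve(m, c(2 * h_full[s], 1))
    list(w = sol[seq_len(ns)], lambda = sol[ns + 1])
  }
  for (iter in seq_len(max_iter)) {
    sol <- kkt_solve(support)
    while (any(sol$w < -tol)) {
      support <- support[-which.min(sol$w)]
      sol <- kkt_solve(support)
    }
    w <- numeric(k)
    w[support] <- pmax(sol$w, 0)
    # reduced gradient of excluded coordinates must be non-negative
    mu <- 2 * (drop(g_full %*% w) - h_full) + sol$lambda
    outside <- setdiff(seq_len(k), support)
    viol <- outside[mu[outside] < -1e-8]
    if (length(viol) == 0L) {
      return(w / sum(w))
    }
    support <- sort(c(support, viol[which.min(mu[viol])]))
  }
  w / sum(w)
}

#' @export
print.histogram_decomposition <- function(x, ...) {
  cat(sprintf(
    "<histogram_decomposition> %d basis histograms | fit RMSE %.4g | %s\n",
    length(x$weights), x$rmse,
    if (x$constrained) "simplex-constrained" else "unconstrained"
  ))
  invisible(x)
}

#' Decomposition RMSE of every material against the others
#'
#' Leave-one-out histogram decomposition: each material's histogram is fit
#' as a convex combination of all other materials' histograms.
#'
#' @param histograms Tibble from [decision_histograms()] covering all
#'   materials.
#' @return A tibble `material_id`, `fit_rmse`.
#' @export
decomposition_rmse <- function(histograms) {
  hm <- histogram_matrix(histograms)
  ids <- as.integer(rownames(hm))
  rmse <- purrr::map_dbl(seq_along(ids), function(i) {
    fit_linear_combination(hm[i, ], hm[-i, , drop = FALSE])$rmse
  })
  tibble::tibble(material_id = ids, fit_rmse = rmse)
}

#' Leave-one-out prediction for an untrained material
#'
#' Trains the avatar network on every material except the held-out one, then
#' predicts activation distributions for the held-out recordings. The
#' held-out material never contributes a training target; its prediction is
#' read purely as a distribution over ranks.
#'
#' @param features Corpus features from [corpus_features()].
#' @param histograms Participant histograms from [decision_histograms()].
#' @param held_out Material id to hold out.
#' @param spec An [avatar_spec()].
#' @param seed Integer seed (weights + shuffling).
#' @param epochs,batch_size Optional training overrides.
#' @return A list: `activations` (matrix, one row per held-out recording),
#'   `mean_activation` (length n_out), `pred_mean` (expected mean rank),
#'   `kurtosis` (of the mean activation), `fit` (the trained `avatar_fit`).
#' @export
leave_one_out_predict <- function(features, histograms, held_out,
                                  spec = avatar_spec(), seed = 1,
                                  epochs = NULL, batch_size = NULL) {
  ids <- unique(features$material_id)
  if (length(ids) < 2L) abort_invalid("need at least 2 materials for leave-one-out")
  if (!held_out %in% ids) abort_invalid("`held_out` is not in the corpus")
  tr <- features$material_id != held_out
  te <- !tr
  targets <- histogram_targets(features$material_id[tr], histograms, spec$loss)
  net <- avatar_net(spec, seed = seed)
  fit <- fit_avatar(net, features$touch[tr, , drop = FALSE],
    features$slide[tr, , drop = FALSE], targets,
    epochs = epochs, batch_size = batch_size, seed = seed)
  act <- predict(fit, features$touch[te, , drop = FALSE],
    features$slide[te, , drop = FALSE])
  mean_act <- colMeans(act)
  list(
    activations = act,
    mean_activation = mean_act,
    pred_mean = sum(seq_along(mean_act) * mean_act),
    kurtosis = histogram_kurtosis(mean_act / sum(mean_act)),
    fit = fit
  )
}

#' Side-versus-middle group summary of a per-material metric
#'
#' Groups a per-material metric into side (outer quarter ranks) and middle
#' (central half) materials, reports group means with standard errors, and a
#' two-sample one-sided location test of the stated direction.
#'
#' @param metrics Tibble with columns `material_id`, `true_rank` and one
#'   metric column.
#' @param metric Name of the metric column.
#' @param alternative Direction of the test on middle relative to side:
#'   `"less"` (default; middle < side, as for generalization errors) or
#'   `"greater"` (as for decision spread).
#' @param n_materials Library size used for the group boundaries.
#' @return A list: `summary` tibble (group, n, mean, sem), `p_value`,
#'   `alternative`.
#' @export
side_vs_middle_summary <- function(metrics, metric,
                                   alternative = c("less", "greater"),
                                   n_materials = max(metrics$true_rank)) {
  alternative <- rlang::arg_match(alternative)
  if (!all(c("material_id", "true_rank", metric) %in% names(metrics))) {
    abort_invalid("`metrics` needs material_id, true_rank and the metric column")
  }
  if (length(unique(metrics$material_id)) < nrow(metrics)) {
    abort_invalid("duplicated materials in `metrics`")
  }
  if (nrow(metrics) < n_materials) {
    abort_invalid("incomplete metric set: one row per material required")
  }
  x <- metrics[[metric]]
  grp <- material_group(metrics$true_rank, n_materials)
  if (length(unique(grp)) < 2L) abort_invalid("metric set does not cover both groups")
  summ <- tibble::tibble(group = grp, value = x) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(), mean = mean(.data$value),
      sem = sd(.data$value) / sqrt(dplyr::n()), .groups = "drop"
    )
  mid <- x[grp == "middle"]; side <- x[grp == "side"]
  p <- if (sd(c(mid, side)) < 1e-12) {
    1 # identical values: no evidence of a difference
  } else {
    t.test(mid, side, alternative = alternative)$p.value
  }
  list(summary = summ, p_value = p, alternative = alternative, metric = metric)
}
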