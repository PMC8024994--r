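#' Sample a synthetic ranking participant
#'
#' Human forced-ranking behaviour is modelled with noisy latent utilities:
#' on each trial the participant's latent value for material m is
#' `true_rank(m) + bias(m) + noise`, and the trial's ranks are the ranks of
#' those latents - so every trial is a full permutation by construction.
#'
#' Two empirical regularities are built in:
#' * middle-ranked materials get a larger noise scale `sigma` than side
#'   materials (more decision confusion where textures are similar);
#' * "S" (similar) participants have smaller bias and noise than "D"
#'   (dissimilar) participants, so a cohort splits into below-average and
#'   above-average decision RMSE groups.
#'
#' Default scales (rank units): S - bias sd 0.8, sigma 1.2 (side) to 2.5
#' (middle); D - bias sd 3, sigma 2 (side) to 4.5 (middle).
#'
#' @param group `"S"` or `"D"`.
#' @param n_materials Number of materials ranked (default 42).
#' @param seed Integer seed.
#' @param bias_sd,sigma_side,sigma_middle Optional overrides of the group
#'   scale parameters.
#' @return A `participant` list with fields `participant_id`, `group`,
#'   `bias` (length-M), `sigma` (length-M), `seed`.
#' @export
#' @examples
#' p <- sample_participant("S", seed = 7)
#' mean(p$sigma[material_group(1:42) == "middle"])
sample_participant <- function(group, n_materials = 42, seed = 1,
                               bias_sd = NULL, sigma_side = NULL,
                               sigma_middle = NULL) {
  if (!is.character(group) || length(group) != 1L || !group %in% c("S", "D")) {
    abort_invalid('`group` must be "S" or "D"')
  }
  m <- check_count(n_materials, "n_materials")
  defaults <- if (group == "S") {
    list(bias_sd = 0.8, sigma_side = 1.2, sigma_middle = 2.5)
  } else {
    list(bias_sd = 3, sigma_side = 2, sigma_middle = 4.5)
  }
  bias_sd <- bias_sd %||% defaults$bias_sd
  sigma_side <- sigma_side %||% defaults$sigma_side
  sigma_middle <- sigma_middle %||% defaults$sigma_middle
  withr::with_seed(derive_seed(seed, paste0("participant-", group)), {
    grp <- material_group(seq_len(m), m)
    sigma <- ifelse(grp == "middle", sigma_middle, sigma_side) *
      exp(rnorm(m, 0, 0.15))
    bias <- rnorm(m, 0, bias_sd)
    structure(
      list(
        participant_id = seed, group = group, n_materials = m,
        bias = bias, sigma = sigma, seed = seed
      ),
      class = "participant"
    )
  })
}

#' @export
print.participant <- function(x, ...) {
  cat(sprintf(
    "<participant %s> group %s | %d materials | mean sigma %.2f\n",
    format(x$participant_id), x$group, x$n_materials, mean(x$sigma)
  ))
  invisible(x)
}

#' Sample a cohort of ranking participants
#'
#' Default composition mirrors the study cohort: 7 similar-deciding (S) and
#' 3 dissimilar-deciding (D) participants.
#'
#' @param n_s,n_d Number of S and D participants.
#' @param n_materials Number of materials ranked.
#' @param seed Integer master seed; participant i uses `seed + i`.
#' @return A list of `participant` objects with unique `participant_id`s.
#' @export
sample_cohort <- function(n_s = 7, n_d = 3, n_materials = 42, seed = 1) {
  groups <- c(rep("S", n_s), rep("D", n_d))
  purrr::imap(groups, function(g, i) {
    p <- sample_participant(g, n_materials, seed = derive_seed(seed, paste0("cohort", i)))
    p$participant_id <- i
    p
  })
}

#' Simulate a participant's ranking trials
#'
#' Each trial draws latent values `true_rank + bias + sigma * noise` per
#' material and ranks them; every trial row is therefore a permutation of
#' 1..M. With all noise and bias zero every trial is the identity permutation.
#'
#' @param participant A [sample_participant()] object.
#' @param n_trials Number of trials (default 20).
#' @param seed Optional seed; defaults to the participant's own seed so the
#'   same participant always produces the same decision matrix.
#' @return A tibble with columns `participant_id`, `group`, `trial`,
#'   `material_id`, `rank`.
#' @export
#' @examples
#' p <- sample_participant("S", 6, seed = 2)
#' d <- simulate_decision_matrix(p, n_trials = 3)
#' all(tapply(d$rank, d$trial, sum) == 21)
simulate_decision_matrix <- function(participant, n_trials = 20, seed = NULL) {
  if (!inherits(participant, "participant")) {
    abort_invalid("`participant` must be a participant object")
  }
  check_count(n_trials, "n_trials")
  m <- participant$n_materials
  seed <- seed %||% participant$seed
  withr::with_seed(derive_seed(seed, "decisions"), {
    rows <- purrr::map(seq_len(n_trials), function(i) {
      latent <- seq_len(m) + participant$bias + rnorm(m, 0, participant$sigma)
      tibble::tibble(
        participant_id = participant$participant_id,
        group = participant$group,
        trial = i,
        material_id = seq_len(m),
        rank = rank(latent, ties.method = "first")
      )
    })
  })
  dplyr::bind_rows(rows)
}

#' Decision matrices for a whole cohort
#'
#' @param cohort A list of participants from [sample_cohort()].
#' @param n_trials Trials per participant (default 20).
#' @return One long tibble of all participants' decisions.
#' @export
cohort_decisions <- function(cohort, n_trials = 20) {
  dplyr::bind_rows(purrr::map(cohort, simulate_decision_matrix, n_trials = n_trials))
}

#' Rank-decision histograms
#'
#' For each material, the fraction of trials assigning it each rank: the
#' soft training target of the avatar network and the unit of all
#' histogram-level comparisons.
#'
#' @param decisions A decision tibble (columns `trial`, `material_id`,
#'   `rank`), typically one participant's.
#' @param n_materials Number of rank bins; defaults to the maximum rank seen.
#' @return A tibble with columns `material_id`, `rank`, `prob`; for every
#'   material the probs sum to 1.
#' @export
#' @examples
#' p <- sample_participant("S", 6, seed = 2)
#' h <- decision_histograms(simulate_decision_matrix(p, 20))
decision_histograms <- function(decisions, n_materials = max(decisions$rank)) {
  if (!is.data.frame(decisions) || nrow(decisions) == 0L) {
    abort_invalid("`decisions` must be a nonempty decision tibble")
  }
  decisions |>
    dplyr::count(.data$material_id, .data$rank) |>
    dplyr::group_by(.data$material_id) |>
    dplyr::mutate(prob = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::select("material_id", "rank", "prob") |>
    tidyr::complete(
      material_id = unique(decisions$material_id),
      rank = seq_len(n_materials),
      fill = list(prob = 0)
    ) |>
    dplyr::arrange(.data$material_id, .data$rank)
}

#' Histogram tibble to materials-by-ranks matrix
#'
#' @param histograms Output of [decision_histograms()].
#' @return A numeric matrix, rows = materials (named by id), cols = ranks.
#' @export
histogram_matrix <- function(histograms) {
  wide <- histograms |>
    dplyr::arrange(.data$material_id, .data$rank) |>
    tidyr::pivot_wider(names_from = "rank", values_from = "prob")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$material_id
  m
}

#' Per-participant tactile decision RMSE against the cohort reference
#'
#' The reference for material m is the grand mean rank over all participants
#' and trials. A participant's decision RMSE is the root mean square, over
#' their trials and all materials, of the deviation of their assigned rank
#' from that reference.
#'
#' @param decisions A cohort decision tibble (columns `participant_id`,
#'   `trial`, `material_id`, `rank`).
#' @param reference Optional reference tibble (`material_id`, `ref`);
#'   computed as the grand mean when `NULL`.
#' @return A tibble `participant_id`, `group` (if present), `rmse`.
#' @export
tactile_decision_rmse <- function(decisions, reference = NULL) {
  if (!is.data.frame(decisions) || nrow(decisions) == 0L) {
    abort_invalid("`decisions` must be a nonempty decision tibble")
  }
  reference <- reference %||% (decisions |>
    dplyr::group_by(.data$material_id) |>
    dplyr::summarise(ref = mean(.data$rank), .groups = "drop"))
  keep <- intersect(c("participant_id", "group"), names(decisions))
  decisions |>
    dplyr::inner_join(reference, by = "material_id") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keep))) |>
    dplyr::summarise(
      rmse = sqrt(mean((.data$rank - .data$ref)^2)),
      .groups = "drop"
    )
}

#' Human-avatar tactile decision RMSE per material
#'
#' For each material, the RMSE across participants between the human
#' trial-mean decision and the paired avatar's trial-mean decision.
#'
#' @param human Decision tibble with columns `participant_id`,
#'   `material_id`, `rank` (trials long).
#' @param avatar Tibble of avatar decisions with the same columns (trials or
#'   a single expected decision per material).
#' @return A tibble `material_id`, `rmse`.
#' @export
h_a_rmse <- function(human, avatar) {
  hm <- human |>
    dplyr::group_by(.data$participant_id, .data$material_id) |>
    dplyr::summarise(human_mean = mean(.data$rank), .groups = "drop")
  am <- avatar |>
    dplyr::group_by(.data$participant_id, .data$material_id) |>
    dplyr::summarise(avatar_mean = mean(.data$rank), .groups = "drop")
  if (!setequal(unique(hm$material_id), unique(am$material_id))) {
    abort_invalid("human and avatar decisions cover different material sets")
  }
  hm |>
    dplyr::inner_join(am, by = c("participant_id", "material_id")) |>
    dplyr::group_by(.data$material_id) |>
    dplyr::summarise(
      rmse = sqrt(mean((.data$human_mean - .data$avatar_mean)^2)),
      .groups = "drop"
    )
}

#' Tactile confusion: per-participant, per-material decision spread
#'
#' Population standard deviation (divisor I, the number of trials) of the
#' ranks a participant assigned to each material over their trials.
#'
#' @param decisions A decision tibble.
#' @return A tibble `participant_id`, `group` (if present), `material_id`,
#'   `std`.
#' @export
decision_std <- function(decisions) {
  n_tr <- length(unique(decisions$trial))
  if (n_tr < 2L) abort_invalid("need at least 2 trials to compute a spread")
  keep <- intersect(c("participant_id", "group"), names(decisions))
  decisions |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keep, "material_id")))) |>
    dplyr::summarise(
      std = sqrt(mean((.data$rank - mean(.data$rank))^2)),
      .groups = "drop"
    )
}

#' Kurtosis of a rank-decision histogram
#'
#' Fourth standardized moment (Pearson convention: a normal shape gives 3)
#' of the rank variable under the histogram's probabilities. Sharper, more
#' confident decisions give larger kurtosis. A zero-variance (one-hot)
#' histogram has no defined kurtosis and returns `NA` with a warning.
#'
#' When comparing against network activations, set `trunc` to a small mass
#' (e.g. 0.005): a softmax output is never exactly zero, and because the
#' fourth moment weights a deviation of 20 ranks by 20^4, residual far-tail
#' leakage of order 1e-3 per node can inflate the kurtosis by an order of
#' magnitude. Truncation zeroes nodes below the threshold and renormalizes
#' before taking moments.
#'
#' @param prob Probability vector over ranks.
#' @param ranks Rank values (default `seq_along(prob)`).
#' @param trunc Mass threshold below which nodes are zeroed before
#'   renormalization (default 0: no truncation).
#' @return A single number, or `NA` for zero-variance histograms.
#' @export
#' @examples
#' histogram_kurtosis(c(0.5, 0, 0.5))
histogram_kurtosis <- function(prob, ranks = seq_along(prob), trunc = 0) {
  check_prob(prob, "prob")
  if (trunc > 0) {
    prob[prob < trunc] <- 0
    prob <- prob / sum(prob)
  }
  mu <- sum(ranks * prob)
  v <- sum((ranks - mu)^2 * prob)
  if (v <= 1e-12) {
    warn("histogram has zero variance; kurtosis undefined")
    return(NA_real_)
  }
  sum((ranks - mu)^4 * prob) / v^2
}

#' Split participants into S and D groups by decision RMSE
#'
#' Participants with RMSE below the cohort mean are labelled S (similar),
#' the rest D (dissimilar). Ties at exactly the mean go to D.
#'
#' @param rmses Tibble from [tactile_decision_rmse()] (columns
#'   `participant_id`, `rmse`).
#' @return The input with a `split` column of `"S"`/`"D"` labels.
#' @export
#' @examples
#' split_groups(tibble::tibble(participant_id = 1:3, rmse = c(1, 1, 4)))
split_groups <- function(rmses) {
  if (!is.data.frame(rmses) || nrow(rmses) < 2L) {
    abort_invalid("need at least 2 participants to split groups")
  }
  dplyr::mutate(rmses, split = ifelse(.data$rmse < mean(.data$rmse), "S", "D"))
}
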