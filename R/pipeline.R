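#' Train a personalized avatar for one participant
#'
#' Convenience wrapper: builds target histogram rows for the training
#' recordings, initializes a seeded network and fits it on the stratified
#' training split.
#'
#' @param features Corpus features from [corpus_features()].
#' @param histograms The participant's [decision_histograms()].
#' @param spec An [avatar_spec()]; its `loss` selects histogram or
#'   categorical training.
#' @param split Optional list with `train`/`test` indices from
#'   [stratified_split()]; when `NULL` the full corpus is used for training.
#' @param seed Integer seed.
#' @param epochs,batch_size Optional training overrides.
#' @return An `avatar_fit` with the split stored as attribute `"split"`.
#' @export
train_avatar <- function(features, histograms, spec = avatar_spec(),
                         split = NULL, seed = 1,
                         epochs = NULL, batch_size = NULL) {
  ix <- split$train %||% seq_along(features$material_id)
  targets <- histogram_targets(features$material_id[ix], histograms, spec$loss)
  net <- avatar_net(spec, seed = seed)
  fit <- fit_avatar(net, features$touch[ix, , drop = FALSE],
    features$slide[ix, , drop = FALSE], targets,
    epochs = epochs, batch_size = batch_size, seed = seed)
  attr(fit, "split") <- split
  fit
}

#' Evaluate avatar decisions on a set of recordings
#'
#' Runs the network on the given recordings, applies the expected-decision
#' rule, and scores against the participant's per-material mean ranks.
#'
#' @param fit A trained `avatar_fit`.
#' @param features Corpus features from [corpus_features()].
#' @param idx Recording indices to evaluate (e.g. the held-out split).
#' @param reference_means Tibble `material_id`, `ref_mean` (the participant's
#'   mean rank per material, kept real-valued).
#' @param tolerance Tolerance level for the headline error (default 2).
#' @param tolerances Grid for the accuracy curve.
#' @return A list: `decisions` tibble (`material_id`, `trial`, `decision`),
#'   `activations` matrix, `error` (at `tolerance`), `accuracy`, `curve`
#'   (an [accuracy_curve()]).
#' @export
evaluate_avatar <- function(fit, features, idx = seq_along(features$material_id),
                            reference_means, tolerance = 2,
                            tolerances = 0:(fit$spec$n_out - 1)) {
  act <- predict(fit, features$touch[idx, , drop = FALSE],
    features$slide[idx, , drop = FALSE])
  decisions <- tibble::tibble(
    material_id = features$material_id[idx],
    trial = features$trial[idx],
    decision = expected_decision(act)
  )
  list(
    decisions = decisions,
    activations = act,
    error = decision_error(decisions, reference_means, tolerance),
    accuracy = tolerance_accuracy(decisions, reference_means, tolerance),
    curve = accuracy_curve(decisions, reference_means, tolerances)
  )
}

#' Per-material mean ranks of a participant
#'
#' @param decisions One participant's decision tibble.
#' @return Tibble `material_id`, `ref_mean`.
#' @export
participant_reference <- function(decisions) {
  decisions |>
    dplyr::group_by(.data$material_id) |>
    dplyr::summarise(ref_mean = mean(.data$rank), .groups = "drop")
}

#' Run the full avatar experiment
#'
#' Orchestrates the pipeline: material library, recording corpus, cohort of
#' ranking participants, per-participant histogram targets, avatar training
#' on a stratified split, and held-out evaluation with the expected-decision
#' rule. All stage seeds derive from the master seed.
#'
#' Scaled-down settings (fewer trials, epochs, participants) run in seconds;
#' the full study conditions (42 materials, 100 recording trials, 10
#' participants) take minutes per participant.
#'
#' @param config A [sim_config()] for the recording corpus.
#' @param n_s,n_d Cohort composition (defaults 7 similar, 3 dissimilar).
#' @param n_rank_trials Ranking trials per participant (default 20).
#' @param spec An [avatar_spec()].
#' @param participants Which participants to train avatars for; default all.
#' @param split_prop Training proportion of the stratified split.
#' @param tolerance Headline tolerance level (default 2).
#' @param seed Master seed.
#' @param epochs,batch_size Optional training overrides.
#' @return A list: `library`, `corpus` config attributes, `cohort`,
#'   `decisions`, `rmse` (with S/D split), `avatars` (per participant:
#'   fit, evaluation, reference).
#' @export
run_experiment <- function(config = sim_config(), n_s = 7, n_d = 3,
                           n_rank_trials = 20, spec = avatar_spec(),
                           participants = NULL, split_prop = 0.8,
                           tolerance = 2, seed = 1,
                           epochs = NULL, batch_size = NULL) {
  config$seed <- derive_seed(seed, "sim")
  library <- tactile_materials(config$n_materials, seed = derive_seed(seed, "lib"))
  corpus <- record_corpus(library, config)
  features <- corpus_features(corpus)
  cohort <- sample_cohort(n_s, n_d, config$n_materials,
    seed = derive_seed(seed, "cohort"))
  decisions <- cohort_decisions(cohort, n_trials = n_rank_trials)
  rmse <- split_groups(tactile_decision_rmse(decisions))
  participants <- participants %||% seq_along(cohort)
  avatars <- purrr::map(participants, function(pid) {
    pdec <- dplyr::filter(decisions, .data$participant_id == pid)
    hist <- decision_histograms(pdec, config$n_materials)
    split <- stratified_split(features$material_id, split_prop,
      seed = derive_seed(seed, paste0("split", pid)))
    fit <- train_avatar(features, hist, spec, split,
      seed = derive_seed(seed, paste0("avatar", pid)),
      epochs = epochs, batch_size = batch_size)
    ref <- participant_reference(pdec)
    eval <- evaluate_avatar(fit, features, split$test, ref, tolerance)
    list(participant_id = pid, fit = fit, histograms = hist,
      reference = ref, evaluation = eval)
  })
  list(
    library = library, features = features, cohort = cohort,
    decisions = decisions, rmse = rmse, avatars = avatars,
    config = config, spec = spec, seed = seed
  )
}
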