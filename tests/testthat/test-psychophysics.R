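test_that("every simulated ranking trial is a permutation", {
  for (seed in 1:5) {
    p <- sample_participant(if (seed %% 2) "S" else "D", 42, seed = seed)
    dec <- simulate_decision_matrix(p, 5)
    sums <- tapply(dec$rank, dec$trial, sum)
    expect_true(all(sums == 42 * 43 / 2))
    full <- tapply(dec$rank, dec$trial, function(r) setequal(r, 1:42))
    expect_true(all(full))
  }
})

test_that("noiseless participants produce the identity permutation", {
  p <- sample_participant("S", 10, seed = 1, bias_sd = 0,
    sigma_side = 0, sigma_middle = 0)
  dec <- simulate_decision_matrix(p, 3)
  expect_true(all(dec$rank == dec$material_id))
  # and their decision spread is identically zero
  expect_true(all(decision_std(dec)$std == 0))
})

test_that("participant generator respects the group structure", {
  expect_error(sample_participant("X"), class = "tactileavatar_invalid_argument")
  expect_identical(sample_participant("S", seed = 5), sample_participant("S", seed = 5))
  # D participants are noisier than S on average, middle noisier than side
  sig_s <- sig_d <- numeric(50)
  for (i in 1:50) {
    sig_s[i] <- mean(sample_participant("S", seed = i)$sigma)
    sig_d[i] <- mean(sample_participant("D", seed = 1000 + i)$sigma)
  }
  expect_gt(mean(sig_d), mean(sig_s))
  grp <- material_group(1:42)
  p <- sample_participant("S", seed = 3)
  expect_gt(mean(p$sigma[grp == "middle"]), mean(p$sigma[grp == "side"]))
})

test_that("decision spread is larger for middle materials across a cohort", {
  # generator calibration over >= 20 participants
  cohort <- sample_cohort(n_s = 14, n_d = 6, seed = 31)
  dec <- cohort_decisions(cohort, n_trials = 8)
  std <- decision_std(dec)
  std$grp <- material_group(std$material_id)
  mid <- std$std[std$grp == "middle"]
  side <- std$std[std$grp == "side"]
  expect_gt(mean(mid), mean(side))
  expect_lt(stats::t.test(mid, side, alternative = "greater")$p.value, 0.01)
})

test_that("decision histograms count ranks and normalize", {
  p <- sample_participant("S", 6, seed = 2)
  dec <- simulate_decision_matrix(p, 20)
  h <- decision_histograms(dec, 6)
  sums <- tapply(h$prob, h$material_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # histogram mean equals the decision-matrix column mean
  hm <- histogram_matrix(h)
  mean_h <- hm %*% (1:6)
  mean_d <- tapply(dec$rank, dec$material_id, mean)
  expect_equal(drop(mean_h), unname(mean_d), ignore_attr = TRUE, tolerance = 1e-12)
  # hand-built cases
  d1 <- tibble::tibble(trial = 1:20, material_id = 1, rank = rep(4, 20))
  h1 <- decision_histograms(d1, 6)
  expect_equal(h1$prob, c(0, 0, 0, 1, 0, 0))
  d2 <- tibble::tibble(trial = 1:20, material_id = 1, rank = rep(c(5, 6), 10))
  h2 <- histogram_matrix(decision_histograms(d2, 6))
  expect_equal(drop(h2), c(0, 0, 0, 0, 0.5, 0.5), ignore_attr = TRUE)
})

test_that("decision RMSE matches a brute-force double sum", {
  # 2 participants x 2 trials x 3 materials, hand-enumerated
  dec <- tibble::tibble(
    participant_id = rep(1:2, each = 6),
    trial = rep(rep(1:2, each = 3), 2),
    material_id = rep(1:3, 4),
    rank = c(
      1, 2, 3, 2, 1, 3, # participant 1
      3, 2, 1, 3, 1, 2 # participant 2
    )
  )
  ref <- tapply(dec$rank, dec$material_id, mean)
  brute <- vapply(1:2, function(s) {
    rows <- dec[dec$participant_id == s, ]
    sqrt(mean((rows$rank - ref[rows$material_id])^2))
  }, numeric(1))
  got <- tactile_decision_rmse(dec)
  expect_equal(got$rmse, brute, tolerance = 1e-12)
  # constant +1 offset from a fixed reference gives RMSE exactly 1
  base <- tibble::tibble(
    participant_id = 1, trial = rep(1:2, each = 3),
    material_id = rep(1:3, 2), rank = rep(1:3, 2) + 1
  )
  ref_tbl <- tibble::tibble(material_id = 1:3, ref = 1:3)
  expect_equal(tactile_decision_rmse(base, ref_tbl)$rmse, 1)
  # participant identical to reference scores 0
  same <- tibble::tibble(
    participant_id = 1, trial = rep(1:2, each = 3),
    material_id = rep(1:3, 2), rank = rep(1:3, 2)
  )
  expect_equal(tactile_decision_rmse(same, ref_tbl)$rmse, 0)
  expect_error(tactile_decision_rmse(same[0, ]), class = "tactileavatar_invalid_argument")
})

test_that("human-avatar RMSE matches direct enumeration", {
  human <- tibble::tibble(
    participant_id = rep(1:2, each = 4),
    trial = rep(rep(1:2, each = 2), 2),
    material_id = rep(1:2, 4),
    rank = c(1, 2, 3, 2, 2, 1, 2, 3)
  )
  avatar_same <- human |> dplyr::group_by(participant_id, material_id) |>
    dplyr::summarise(rank = mean(rank), .groups = "drop") |>
    dplyr::mutate(trial = 1)
  expect_true(all(h_a_rmse(human, avatar_same)$rmse < 1e-12))
  # single participant, avatar off by 2 ranks on material 1
  h1 <- human[human$participant_id == 1, ]
  a1 <- avatar_same[avatar_same$participant_id == 1, ]
  a1$rank[a1$material_id == 1] <- a1$rank[a1$material_id == 1] + 2
  got <- h_a_rmse(h1, a1)
  expect_equal(got$rmse[got$material_id == 1], 2)
  expect_equal(got$rmse[got$material_id == 2], 0)
  # brute force on the 2-participant case with a perturbed avatar
  a2 <- avatar_same
  a2$rank <- a2$rank + c(0.5, -1, 2, 0)
  brute <- vapply(1:2, function(m) {
    hm <- tapply(human$rank[human$material_id == m],
      human$participant_id[human$material_id == m], mean)
    am <- a2$rank[a2$material_id == m][order(a2$participant_id[a2$material_id == m])]
    sqrt(mean((hm - am)^2))
  }, numeric(1))
  expect_equal(h_a_rmse(human, a2)$rmse, brute, tolerance = 1e-12)
  bad <- a2[a2$material_id == 1, ]
  expect_error(h_a_rmse(human, bad), class = "tactileavatar_invalid_argument")
})

test_that("decision spread uses the population (1/I) convention", {
  d <- tibble::tibble(
    participant_id = 1, trial = 1:2, material_id = 1, rank = c(4, 6)
  )
  expect_equal(decision_std(d)$std, 1) # not the sample sd sqrt(2)
  # textbook formula oracle on a random matrix
  p <- sample_participant("D", 8, seed = 4)
  dec <- simulate_decision_matrix(p, 10)
  got <- decision_std(dec)
  oracle <- vapply(seq_len(nrow(got)), function(i) {
    r <- dec$rank[dec$material_id == got$material_id[i]]
    sqrt(sum((r - mean(r))^2) / length(r))
  }, numeric(1))
  expect_equal(got$std, oracle, tolerance = 1e-12)
  expect_error(decision_std(d[1, ]), class = "tactileavatar_invalid_argument")
})

test_that("histogram kurtosis follows the Pearson convention", {
  # symmetric two-point distribution: kurtosis exactly 1
  expect_equal(histogram_kurtosis(c(0.5, 0, 0.5)), 1)
  # matched-support: a peaked histogram beats the uniform
  ranks <- 1:9
  peaked <- dnorm(ranks, 5, 1); peaked <- peaked / sum(peaked)
  unif <- rep(1 / 9, 9)
  expect_gt(histogram_kurtosis(peaked), histogram_kurtosis(unif))
  # numeric moments oracle
  mu <- sum(ranks * peaked); v <- sum((ranks - mu)^2 * peaked)
  expect_equal(histogram_kurtosis(peaked),
    sum((ranks - mu)^4 * peaked) / v^2, tolerance = 1e-12)
  # degenerate one-hot: undefined, reported as NA with a warning
  expect_warning(k <- histogram_kurtosis(c(0, 1, 0)))
  expect_true(is.na(k))
})

test_that("group split thresholds at the cohort mean RMSE", {
  r <- tibble::tibble(participant_id = 1:3, rmse = c(1, 1, 4))
  expect_equal(split_groups(r)$split, c("S", "S", "D"))
  # ties at the mean go to D
  r2 <- tibble::tibble(participant_id = 1:3, rmse = c(2, 2, 2))
  expect_equal(split_groups(r2)$split, rep("D", 3))
  expect_error(split_groups(r[1, ]), class = "tactileavatar_invalid_argument")
})

test_that("default cohort reproduces the 7 S / 3 D composition", {
  cohort <- sample_cohort(seed = 1)
  expect_length(cohort, 10)
  dec <- cohort_decisions(cohort, n_trials = 20)
  rmse <- split_groups(tactile_decision_rmse(dec))
  expect_equal(sum(rmse$split == "S"), 7)
  expect_equal(sum(rmse$split == "D"), 3)
  # the generated S/D labels agree with the RMSE-based split
  expect_equal(rmse$split, rmse$group)
})
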