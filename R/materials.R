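#' Build a ranked library of tactile texture materials
#'
#' Generates `n_materials` synthetic fabric-like materials ordered from
#' smoothest/softest (rank 1) to roughest (rank `n_materials`). Each material
#' carries the physical ground truth the simulator needs:
#'
#' * `durometer`: indentation hardness on the 20-90 durometer scale. Hardness
#'   is deliberately *not* correlated with roughness rank (a smooth fabric can
#'   be hard), so the library assigns a seeded permutation of values spanning
#'   20-90.
#' * `hardness_bin`: the 5-level binning of durometer readings
#'   (1: 20-40, 2: 41-50, 3: 51-60, 4: 61-70, 5: 71-90).
#' * `pitch_um`: spatial period of the surface pattern in micrometres,
#'   log-spaced over roughly 100-10000 um and increasing with rank. Ranks are
#'   placed on a normal-quantile grid, so middle-ranked materials sit closer
#'   together in texture space than side materials - the property that makes
#'   middle materials harder to tell apart.
#' * `roughness`: broadband (stochastic) surface roughness level, nondecreasing
#'   in rank; scales the aperiodic component of the sliding signal, in volts.
#' * `harmonics`: list-column of relative harmonic amplitudes of the periodic
#'   sliding component (fundamental first, geometric decay).
#' * `piezo_gain`: per-material electromechanical coupling factor (jitter
#'   around 1) multiplying every simulated voltage.
#'
#' @param n_materials Number of materials (default 42).
#' @param seed Integer seed; the same seed always yields the same library.
#' @return A tibble with one row per material, columns `material_id`,
#'   `true_rank`, `durometer`, `hardness_bin`, `pitch_um`, `roughness`,
#'   `harmonics` (list), `piezo_gain`.
#' @export
#' @examples
#' lib <- tactile_materials(8, seed = 1)
#' lib
tactile_materials <- function(n_materials = 42, seed = 1) {
  n <- check_count(n_materials, "n_materials")
  withr::with_seed(derive_seed(seed, "materials"), {
    rank <- seq_len(n)
    # normal-quantile placement: texture coordinate gaps shrink in the middle
    u <- if (n == 1) 0.5 else {
      t <- qnorm(rank / (n + 1))
      (t - min(t)) / (max(t) - min(t))
    }
    jit <- rnorm(n, 0, 0.015)
    pitch <- 10^(2 + 2 * u + jit)
    rough <- 0.02 + 0.22 * u
    duro <- if (n == 1) 55 else sample(seq(20, 90, length.out = n))
    gain <- exp(rnorm(n, 0, 0.05))
    harm <- purrr::map(rank, function(r) 0.35^(0:2))
    tibble::tibble(
      material_id = rank,
      true_rank = rank,
      durometer = duro,
      hardness_bin = hardness_bin(duro),
      pitch_um = pitch,
      roughness = rough,
      harmonics = harm,
      piezo_gain = gain
    )
  })
}

#' Bin a durometer hardness reading into the 5 standard levels
#'
#' Levels: 1 for 20-40, 2 for 41-50, 3 for 51-60, 4 for 61-70, 5 for 71-90.
#'
#' @param durometer Numeric vector of durometer readings.
#' @return Integer vector of bins in 1..5.
#' @export
#' @examples
#' hardness_bin(c(24.9, 45, 55, 65, 85.1))
hardness_bin <- function(durometer) {
  if (!is.numeric(durometer) || anyNA(durometer)) {
    abort_invalid("`durometer` must be numeric without NAs")
  }
  as.integer(cut(durometer, breaks = c(-Inf, 40, 50, 60, 70, Inf)))
}

#' Side/middle material grouping
#'
#' Middle-ranked materials (ranks 11-30 of 42) elicit more decision confusion
#' than side materials (ranks 1-10 and 31-42). For libraries of other sizes
#' the same proportions are used: middle is the central half of the rank
#' range, sides are the outer quarters.
#'
#' @param true_rank Integer vector of ranks.
#' @param n_materials Library size (default 42).
#' @return Character vector, `"side"` or `"middle"`.
#' @export
#' @examples
#' table(material_group(1:42))
material_group <- function(true_rank, n_materials = 42) {
  lo <- floor(n_materials * 10 / 42)
  hi <- floor(n_materials * 30 / 42)
  ifelse(true_rank > lo & true_rank <= hi, "middle", "side")
}
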