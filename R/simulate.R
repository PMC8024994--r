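#' Simulation configuration
#'
#' Bundles the physical and noise parameters of the piezoelectric recording
#' simulator. Defaults mirror the measurement conditions the system is built
#' around: 42 materials, 100 trials per material, 1.2 N contact force,
#' 4 cm/s sliding velocity, 1000 samples/s.
#'
#' @param n_materials Number of materials in the library.
#' @param n_trials_per_material Recordings per material (default 100).
#' @param contact_force Contact force in newtons (default 1.2).
#' @param sliding_velocity Sliding velocity in cm/s (default 4).
#' @param noise Relative noise level: per-cell additive white-noise standard
#'   deviation as a fraction of the reference amplitude `v_ref` (default 0.1).
#' @param n_cells Active sensing cells in the array (default 30); the stored
#'   aggregated trace is their mean.
#' @param sample_rate Sampling rate, 1/s (default 1000).
#' @param touch_duration Touch-trace length in seconds (default 0.6).
#' @param slide_duration Slide-trace length in seconds (default 2).
#' @param onset_time Contact-onset time within the touch trace, seconds
#'   (default 0.05).
#' @param rise_time Rise time from contact to the touch peak, seconds
#'   (default 0.05).
#' @param decay_tau Exponential decay constant of the touch transient after
#'   its peak, seconds (default 0.1).
#' @param slope_gain Affine slope-vs-hardness map `slope = piezo_gain * force
#'   * (slope_offset + slope_gain * durometer)` in V/s per N per durometer
#'   unit (default 0.01).
#' @param slope_offset Intercept of the slope map (default 0).
#' @param slide_amp Amplitude of the fundamental sliding oscillation, volts
#'   (default 0.5).
#' @param v_ref Reference amplitude used to scale the noise level, volts
#'   (default 0.05).
#' @param cell_gain_sd Standard deviation of per-cell multiplicative gain
#'   jitter (default 0.02).
#' @param seed Integer seed for the corpus noise stream.
#' @return A `sim_config` list.
#' @export
#' @examples
#' sim_config(n_materials = 6, n_trials_per_material = 4)
sim_config <- function(n_materials = 42,
                       n_trials_per_material = 100,
                       contact_force = 1.2,
                       sliding_velocity = 4,
                       noise = 0.1,
                       n_cells = 30,
                       sample_rate = 1000,
                       touch_duration = 0.6,
                       slide_duration = 2,
                       onset_time = 0.05,
                       rise_time = 0.05,
                       decay_tau = 0.1,
                       slope_gain = 0.01,
                       slope_offset = 0,
                       slide_amp = 0.5,
                       v_ref = 0.05,
                       cell_gain_sd = 0.02,
                       seed = 1) {
  check_count(n_materials, "n_materials")
  check_count(n_trials_per_material, "n_trials_per_material")
  check_number(contact_force, "contact_force", min = 0)
  check_number(sliding_velocity, "sliding_velocity", min = 0, strict = TRUE)
  check_number(noise, "noise", min = 0)
  check_count(n_cells, "n_cells")
  structure(
    list(
      n_materials = as.integer(n_materials),
      n_trials_per_material = as.integer(n_trials_per_material),
      contact_force = contact_force,
      sliding_velocity = sliding_velocity,
      noise = noise,
      n_cells = as.integer(n_cells),
      sample_rate = sample_rate,
      touch_duration = touch_duration,
      slide_duration = slide_duration,
      onset_time = onset_time,
      rise_time = rise_time,
      decay_tau = decay_tau,
      slope_gain = slope_gain,
      slope_offset = slope_offset,
      slide_amp = slide_amp,
      v_ref = v_ref,
      cell_gain_sd = cell_gain_sd,
      seed = seed
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf(
    "  %d materials x %d trials | force %.2g N | velocity %.2g cm/s | noise %.2g\n",
    x$n_materials, x$n_trials_per_material, x$contact_force,
    x$sliding_velocity, x$noise
  ))
  cat(sprintf(
    "  %d cells @ %g samples/s | touch %gs (onset %gs) | slide %gs | seed %s\n",
    x$n_cells, x$sample_rate, x$touch_duration, x$onset_time,
    x$slide_duration, format(x$seed)
  ))
  invisible(x)
}

# deterministic per-material phase for the sliding fundamental + harmonics,
# so that trial-to-trial variation comes only from the noise stream
material_phases <- function(material_id, n_harm) {
  h <- seq_len(n_harm)
  2 * pi * ((material_id * 0.6180339887 * h + 0.1 * h^2) %% 1)
}

# noiseless single-cell touch transient: linear rise at the hardness-coded
# slope, then exponential decay from the peak
touch_signal <- function(material, force, config) {
  n <- round(config$touch_duration * config$sample_rate)
  t <- (seq_len(n) - 1) / config$sample_rate
  slope <- material$piezo_gain * force *
    (config$slope_offset + config$slope_gain * material$durometer)
  t0 <- config$onset_time
  tp <- t0 + config$rise_time
  peak <- slope * config$rise_time
  v <- numeric(n)
  rise <- t >= t0 & t < tp
  v[rise] <- slope * (t[rise] - t0)
  dec <- t >= tp
  v[dec] <- peak * exp(-(t[dec] - tp) / config$decay_tau)
  v
}

# noiseless single-cell sliding signal: fundamental at velocity/pitch plus
# geometrically decaying harmonics (deterministic phases per material)
slide_signal <- function(material, velocity, duration, config) {
  n <- round(duration * config$sample_rate)
  t <- (seq_len(n) - 1) / config$sample_rate
  f0 <- velocity * 1e4 / material$pitch_um # cm/s over um -> Hz
  amps <- config$slide_amp * material$harmonics[[1]]
  ph <- material_phases(material$material_id, length(amps))
  v <- numeric(n)
  for (h in seq_along(amps)) {
    v <- v + material$piezo_gain * amps[h] * sin(2 * pi * h * f0 * t + ph[h])
  }
  v
}

as_material_row <- function(material) {
  if (!is.data.frame(material) || nrow(material) != 1L) {
    abort_invalid("`material` must be a single material row (1-row tibble)")
  }
  material
}

#' Simulate a piezoelectric touch transient
#'
#' Produces the aggregated (mean over cells) voltage trace of one touch event.
#' The initial slope of the transient is `piezo_gain * force *
#' (slope_offset + slope_gain * durometer)`: strictly increasing in durometer
#' hardness at fixed force. Additive white noise per cell is scaled by
#' `config$noise * config$v_ref`; zero force with nonzero noise gives a pure
#' zero-mean noise trace.
#'
#' @param material One row of [tactile_materials()].
#' @param force Contact force in newtons (default from `config`).
#' @param config A [sim_config()].
#' @param cells If `TRUE`, return the full cells-by-samples matrix with the
#'   aggregated trace as attribute `"aggregated"`; otherwise the aggregated
#'   numeric trace.
#' @return Numeric trace (volts), or a matrix when `cells = TRUE`.
#' @export
#' @examples
#' lib <- tactile_materials(4, seed = 1)
#' tr <- simulate_touch(lib[1, ], config = sim_config(noise = 0))
#' length(tr)
simulate_touch <- function(material, force = config$contact_force,
                           config = sim_config(), cells = FALSE) {
  material <- as_material_row(material)
  if (!is.numeric(force) || length(force) != 1L || is.na(force) || force < 0) {
    abort_invalid("`force` must be a single number >= 0")
  }
  base <- touch_signal(material, force, config)
  traces <- cell_traces(base, config)
  if (cells) traces else attr(traces, "aggregated")
}

#' Simulate a piezoelectric sliding signal
#'
#' Produces the aggregated voltage trace recorded while sliding over the
#' material at the given velocity. The dominant oscillation sits at
#' `velocity / pitch` (4 cm/s over a 400 um pitch gives 100 Hz, i.e. a 0.01 s
#' inter-peak interval); harmonics decay geometrically and broadband
#' roughness noise grows with the material's roughness level.
#'
#' @inheritParams simulate_touch
#' @param velocity Sliding velocity in cm/s; must be positive.
#' @param duration Trace duration in seconds; must be positive.
#' @return Numeric trace (volts), or a matrix when `cells = TRUE`.
#' @export
#' @examples
#' lib <- tactile_materials(4, seed = 1)
#' tr <- simulate_slide(lib[2, ], config = sim_config(noise = 0))
simulate_slide <- function(material, velocity = config$sliding_velocity,
                           duration = config$slide_duration,
                           config = sim_config(), cells = FALSE) {
  material <- as_material_row(material)
  check_number(velocity, "velocity", min = 0, strict = TRUE)
  check_number(duration, "duration", min = 0, strict = TRUE)
  base <- slide_signal(material, velocity, duration, config)
  traces <- cell_traces(base, config, roughness = material$roughness)
  if (cells) traces else attr(traces, "aggregated")
}

# replicate a base signal over cells with gain jitter + white noise
# (+ shared broadband roughness for sliding), aggregate by mean
cell_traces <- function(base, config, roughness = 0) {
  nc <- config$n_cells
  n <- length(base)
  gains <- 1 + rnorm(nc, 0, config$cell_gain_sd) * (config$noise > 0)
  m <- outer(gains, base)
  if (roughness > 0 && config$noise > 0) {
    m <- m + matrix(rnorm(n, 0, roughness), nc, n, byrow = TRUE)
  }
  if (config$noise > 0) {
    m <- m + matrix(rnorm(nc * n, 0, config$noise * config$v_ref), nc, n)
  }
  structure(m, aggregated = colMeans(m))
}

#' Record a full corpus of touch/slide trials
#'
#' Runs `n_trials_per_material` touch-and-slide contact events for every
#' material in the library. Trial-to-trial variation comes only from the
#' seeded noise stream: a fixed config and seed reproduce the corpus exactly,
#' and at noise 0 all trials of a material are identical. Only the aggregated
#' (mean over cells) traces are stored.
#'
#' @param library A material library from [tactile_materials()].
#' @param config A [sim_config()].
#' @return A tibble with columns `material_id`, `trial`, `touch` and `slide`
#'   (list-columns of numeric traces), carrying the config as attribute
#'   `"config"`.
#' @export
#' @examples
#' lib <- tactile_materials(3, seed = 1)
#' corpus <- record_corpus(lib, sim_config(n_materials = 3, n_trials_per_material = 2))
#' nrow(corpus)
record_corpus <- function(library, config = sim_config()) {
  if (!is.data.frame(library) || nrow(library) == 0L) {
    abort_invalid("`library` must be a nonempty material library")
  }
  nt <- config$n_trials_per_material
  withr::with_seed(derive_seed(config$seed, "corpus"), {
    rows <- purrr::map(seq_len(nrow(library)), function(i) {
      mat <- library[i, ]
      touch <- vector("list", nt)
      slide <- vector("list", nt)
      for (j in seq_len(nt)) {
        touch[[j]] <- simulate_touch(mat, config$contact_force, config)
        slide[[j]] <- simulate_slide(mat, config$sliding_velocity,
          config$slide_duration, config)
      }
      tibble::tibble(
        material_id = mat$material_id, trial = seq_len(nt),
        touch = touch, slide = slide
      )
    })
  })
  corpus <- dplyr::bind_rows(rows)
  attr(corpus, "config") <- config
  corpus
}
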