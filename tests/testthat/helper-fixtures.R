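# shared fixtures, built once per test run and cached
.fixtures <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

# small noisy corpus: full 42-material library, few trials
small_corpus <- function() {
  cached("small_corpus", function() {
    cfg <- sim_config(n_materials = 42, n_trials_per_material = 6, seed = 11)
    lib <- tactile_materials(42, seed = 11)
    corpus <- record_corpus(lib, cfg)
    list(cfg = cfg, lib = lib, corpus = corpus,
      features = corpus_features(corpus))
  })
}

# nearly clean corpus for moment-preservation checks
clean_corpus <- function() {
  cached("clean_corpus", function() {
    cfg <- sim_config(n_materials = 42, n_trials_per_material = 6,
      noise = 0.02, seed = 12)
    lib <- tactile_materials(42, seed = 12)
    corpus <- record_corpus(lib, cfg)
    list(cfg = cfg, lib = lib, corpus = corpus,
      features = corpus_features(corpus))
  })
}

fixture_participant <- function() {
  cached("participant", function() {
    p <- sample_participant("S", 42, seed = 21)
    dec <- simulate_decision_matrix(p, 20)
    list(p = p, dec = dec, hist = decision_histograms(dec, 42),
      ref = participant_reference(dec))
  })
}

# a material row with full control over physics, for targeted simulations
test_material <- function(pitch_um = 4000, durometer = 55, roughness = 0.05,
                          harmonics = c(1, 0, 0), piezo_gain = 1,
                          material_id = 1L, true_rank = 1L) {
  tibble::tibble(
    material_id = material_id, true_rank = true_rank, durometer = durometer,
    hardness_bin = hardness_bin(durometer), pitch_um = pitch_um,
    roughness = roughness, harmonics = list(harmonics), piezo_gain = piezo_gain
  )
}

# tiny network spec that trains in well under a second
tiny_spec <- function(...) {
  avatar_spec(n_out = 5, touch_len = 24, slide_len = 16, conv_channels = 3,
    slide_units = c(8, 6), trunk_units = c(10, 7), ...)
}
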