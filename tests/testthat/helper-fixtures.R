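# shared fixtures built in code; heavyweight objects are created once per
# test file through these helpers

# reduced raster and its filter bank (cached per file)
fixture_bank <- local({
  cache <- new.env(parent = emptyenv())
  function(size_px = 64L) {
    key <- as.character(size_px)
    if (is.null(cache[[key]])) {
      cache[[key]] <- build_filter_bank(reduced_stimulus_params(size_px))
    }
    cache[[key]]
  }
})

# an all-zero-contrast single-environment design (used by observer and
# reverse-correlation tests): prev-stimulus structure from a Markov chain
zero_contrast_design <- function(n, env = "repeating", p_rep = 0.8, seed = 1L) {
  ori <- if (env == "repeating") {
    generate_markov_sequence(n, p_rep, tolerance = 0.02, seed = seed)$orientation
  } else {
    set.seed(seed)
    sample(c(-1, 1), n, replace = TRUE)
  }
  des <- data.frame(environment = env, block = 1L, trial = seq_len(n),
                    orientation = ori, contrast = 0, correct_label = ori)
  if (env == "neutral") {
    set.seed(seed + 1L)
    des$correct_label <- sample(c(-1, 1), n, replace = TRUE)
  }
  des
}

# render + energies for a zero-contrast design at the reduced raster
design_energies <- function(des, bank, seed = 1L) {
  sp <- bank$params
  imgs <- lapply(des$trial, function(t)
    render_stimulus(0, 0, sp, seed = derive_seed(seed, paste0("stim:", t))))
  E <- compute_energy_profiles(imgs, bank)
  list(energy = E, net = cbind(trial = des$trial, class_net_energies(E)))
}
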