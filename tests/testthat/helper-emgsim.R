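# Shared fixtures: built in code, deterministic.

cfg <- emgsim::default_config()

# midrange condition vector used as the baseline for parameter sweeps
mid_cond <- function(...) {
  args <- list(fat_conductivity = 0.5, fibre_number = 0.5, depth = 0.5,
               ml_pos = 0.5, iz_pos = 0.5, cv = 0.5, fibre_length = 0.5)
  args[names(list(...))] <- list(...)
  do.call(emgsim::condition_vector, args)
}

# fast template: shorter time axis than the default
quick_muap <- function(cond, latent = NULL, T = 96, fs = 2048) {
  emgsim::generate_muap(cond, latent, fs, T, cfg)
}

# two-muscle toy set for static-optimization tests
toy_muscle <- function(name, r, fmax = 300, lopt = 0.06, slack = 0.2) {
  list(name = name, optimal_fibre_length = lopt, tendon_slack_length = slack,
       max_isometric_force = fmax, moment_arms = list(wrist_flexion = r),
       territory_centre_depth = 8, territory_radius = 5, ml_angle = 90,
       n_units = 4, total_fibres = 1000, fibre_length_mm = 60)
}

# constant-angle trajectory over the full DoF schema
flat_traj <- function(n = 5, fs = 50, set = c()) {
  ang <- matrix(0, n, length(cfg$dof$names),
                dimnames = list(NULL, cfg$dof$names))
  for (d in names(set)) ang[, d] <- set[[d]]
  emgsim::joint_trajectory((seq_len(n) - 1) / fs, ang, fs)
}

# temp file path for IO round-trip tests
scratch_file <- function(name) file.path(tempdir(), name)

# dense convolution oracle: FFT convolution of the spike indicator with each
# channel's (static) template, independent of the shift-and-add synthesis
oracle_emg <- function(trains, templates, fs, duration) {
  n <- round(duration * fs)
  out <- matrix(0, 320, n)
  for (k in seq_along(trains)) {
    if (!length(trains[[k]])) next
    delta <- tabulate(round(trains[[k]] * fs) + 1, nbins = n)
    flat <- emgsim::flatten_muap(templates[[k]])
    for (ch in 1:320) {
      full <- stats::convolve(delta, rev(flat[ch, ]), type = "open")
      out[ch, ] <- out[ch, ] + full[seq_len(n)]
    }
  }
  out
}
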