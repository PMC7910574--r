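# shared fixtures: small/fast configurations used across test files

fast_config <- function(...) {
  sim_config(n_nodes = 31, ...)
}

# a clean pulsatile synthetic trace: two proportional channels with a
# cardiac-like modulation, 100 Hz
clean_trace <- function(duration_s = 30, fs = 100, ratio = 1.2) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  base <- 2 + 0.3 * sin(2 * pi * t)
  doppler_trace(ratio * base, base, fs_hz = fs)
}

# one subject profile as a plain list (what generate_* expect)
profile_row <- function(spec, i) as.list(spec$subjects[i, ])
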