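# Shared fixtures, built once per test run and cached across files.
# The canonical model (3 lower + 2 higher channels, 16 Hz, r = 0.9,
# top-down couplings 0.25 and 0.15 at lag 1) is the stated reference world;
# every tolerance below derives from its closed-form spectra.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

grid1 <- function() seq(5, 90, by = 1)

# 5000 canonical trials (contrast 0 => both conditions share the base
# coupling), mean-subtracted; the workhorse estimation fixture.
canon_ens <- function() cached("canon_ens", {
  subtract_ensemble_mean(simulate_trials(
    canonical_conditions(trials_per_condition = 2500L, contrast = 0,
                         seed = 7L)))
})

# Closed-form truth for the coupled pair (L1, H1) on the 1 Hz grid.
canon_truth <- function() cached("canon_truth",
  model_spectra(true_pair_model(canonical_network(), "L1", "H1"), grid1()))

# Order-10 fit of the coupled pair on the canonical ensemble.
canon_fit <- function() cached("canon_fit",
  pair_spectra(canon_ens(), c(1L, 4L), order = 10L, freqs = grid1()))

# B = 200 paired bootstrap spectra over all 6 lower-higher pairs.
canon_boot <- function() cached("canon_boot",
  bootstrap_spectra(canon_ens(), area_pairs(canon_ens()), order = 10L,
                    freqs = grid1(), B = 200L, seed = 3L))

# Two-channel white-noise ensemble (r = 0, no coupling).
white_ens <- function(ntr = 2000L, ns = 17L, seed = 1L) {
  base <- network_spec(1, 1, osc_freq = 16, osc_damping = 0,
                       sampling_rate = 200)
  subtract_ensemble_mean(simulate_trials(condition_pair_spec(
    base, trials_per_condition = ntr %/% 2L, samples_per_trial = ns,
    seed = seed)))
}

# Uncoupled 16 Hz oscillator pair (the hard null: narrowband but
# independent channels).
null_osc_ens <- function(ntr = 400L, seed = 1L) {
  base <- network_spec(1, 1, osc_freq = 16, osc_damping = 0.9,
                       sampling_rate = 200)
  subtract_ensemble_mean(simulate_trials(condition_pair_spec(
    base, trials_per_condition = ntr %/% 2L, seed = seed)))
}

# Common-input fixture: independent oscillators mixed instantaneously;
# true directed GC is zero in both directions.
mixing_ens <- function(ntr = 1000L, seed = 1L) {
  base <- network_spec(1, 1, osc_freq = 16, osc_damping = 0.9,
                       mixing = matrix(c(1, 0.5, 0.5, 1), 2))
  subtract_ensemble_mean(simulate_trials(condition_pair_spec(
    base, trials_per_condition = ntr %/% 2L, seed = seed)))
}

# Single coupled pair (H1 -> L1, 0.25 at lag 1): the positive control.
coupled_pair_ens <- function(ntr = 1000L, seed = 1L) {
  base <- network_spec(1, 1, osc_freq = 16, osc_damping = 0.9,
                       coupling = data.frame(from = "H1", to = "L1",
                                             lag = 1L, coef = 0.25))
  subtract_ensemble_mean(simulate_trials(condition_pair_spec(
    base, trials_per_condition = ntr %/% 2L, seed = seed)))
}

# Concatenate two trial arrays along the trial axis.
abind_trials <- function(a, b) {
  out <- array(0, dim = c(dim(a)[1] + dim(b)[1], dim(a)[2], dim(a)[3]))
  if (dim(a)[1]) out[seq_len(dim(a)[1]), , ] <- a
  if (dim(b)[1]) out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}
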