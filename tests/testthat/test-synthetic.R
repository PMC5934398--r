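test_that("build_var realizes specs exactly and enforces stationarity", {
  # degenerate spec: no damping, no coupling -> pure white noise
  flat <- network_spec(1, 1, osc_freq = 16, osc_damping = 0)
  net <- build_var(flat)
  expect_true(all(net$A == 0))
  expect_identical(net$Sigma, diag(2))

  # canonical resonator coefficients and coupling placement
  net <- build_var(canonical_network())
  r <- 0.9
  expect_equal(net$A[1, 1, 1], 2 * r * cos(2 * pi * 16 / 200))
  expect_equal(net$A[1, 1, 2], -r^2)
  expect_equal(net$A[1, 4, 1], 0.25)  # H1 -> L1
  expect_equal(net$A[2, 5, 1], 0.15)  # H2 -> L2
  expect_lt(companion_spectral_radius(net$A), 1)

  # non-stationary spec raises an error naming the spectral radius
  bad <- network_spec(1, 1, osc_freq = 16, osc_damping = 0.9,
                      coupling = data.frame(from = c("H1", "L1"),
                                            to = c("L1", "H1"),
                                            lag = 1L, coef = c(2, 2)))
  expect_error(build_var(bad), "spectral radius")
})

test_that("true canonical spectrum peaks within 1 Hz of 16 Hz (0.1 Hz grid)", {
  tm <- true_pair_model(canonical_network(), "L1", "H1")
  fr <- seq(5, 90, by = 0.1)
  sp <- model_spectra(tm, fr)
  expect_lt(abs(fr[which.max(sp$sgc[, 1])] - 16), 1)
  # bottom-up truth is exactly zero
  expect_lt(max(sp$sgc[, 2]), 1e-10)
})

test_that("simulate_trials is deterministic and handles empty specs", {
  spec <- canonical_conditions(trials_per_condition = 20L, seed = 42L)
  e1 <- simulate_trials(spec)
  e2 <- simulate_trials(spec)
  expect_identical(e1$data, e2$data)
  expect_identical(e1$condition, e2$condition)

  empty <- canonical_conditions(trials_per_condition = 0L, seed = 1L)
  ee <- simulate_trials(empty)
  expect_identical(dim(ee$data), c(0L, 5L, 17L))
  expect_length(ee$channel_labels, 5L)
  expect_true(all(ee$area %in% c("lower", "higher")))
})

test_that("lag-1 coupling leaves the predicted cross-correlation signature", {
  make <- function(coef) {
    cp <- if (coef == 0) NULL else
      data.frame(from = "H1", to = "L1", lag = 1L, coef = coef)
    base <- network_spec(1, 1, osc_freq = 16, osc_damping = 0.9,
                         coupling = cp)
    simulate_trials(condition_pair_spec(base, trials_per_condition = 1000L,
                                        seed = 5L))
  }
  zstat <- function(ens) {
    x <- ens$data[, 1, -1]                 # L1 at t
    y <- ens$data[, 2, -dim(ens$data)[3]]  # H1 at t - 1
    r <- stats::cor(as.vector(x), as.vector(y))
    r * sqrt(length(x))                    # SE under independence = 1/sqrt(N)
  }
  expect_gt(abs(zstat(make(0.25))), 5)
  expect_lt(abs(zstat(make(0))), 5)
})

test_that("the pinking filter produces a ~1/f power spectrum", {
  set.seed(2)
  w <- matrix(rnorm(4096 * 20), 4096)
  pk <- betaflow:::pink_filter(w)
  pg <- apply(pk[-(1:512), ], 2, function(x)
    spec.pgram(x, plot = FALSE, taper = 0, detrend = FALSE)$spec)
  fr <- spec.pgram(pk[-(1:512), 1], plot = FALSE, taper = 0,
                   detrend = FALSE)$freq * 200
  keep <- fr >= 2 & fr <= 50
  slope <- unname(stats::coef(
    stats::lm(log10(rowMeans(pg)[keep]) ~ log10(fr[keep])))[2])
  expect_lt(slope, -0.6)   # power falls roughly as 1/f
  expect_gt(slope, -1.4)

  # and the generator mixes it in at the requested gain
  base <- network_spec(1, 0, osc_freq = 16, osc_damping = 0,
                       pink_noise_gain = 5)
  ens <- simulate_trials(condition_pair_spec(
    base, trials_per_condition = 100L, samples_per_trial = 17L, seed = 2L))
  base0 <- network_spec(1, 0, osc_freq = 16, osc_damping = 0)
  ens0 <- simulate_trials(condition_pair_spec(
    base0, trials_per_condition = 100L, samples_per_trial = 17L, seed = 2L))
  expect_gt(stats::var(as.vector(ens$data)),
            stats::var(as.vector(ens0$data)))
})

test_that("condition deltas only accept top-down edges and scale coupling", {
  base <- canonical_network()
  expect_error(condition_pair_spec(base, condition_deltas = list(
    contingency1 = data.frame(from = "L1", to = "H1", lag = 1L, factor = 2),
    contingency2 = data.frame(from = character(), to = character(),
                              lag = integer(), factor = numeric()))),
    "top-down")
  spec <- canonical_conditions(trials_per_condition = 5L, contrast = 0.3)
  m1 <- build_var(betaflow:::apply_deltas(base,
                                          spec$condition_deltas$contingency1))
  expect_equal(m1$A[1, 4, 1], 0.25 * 1.3)
})
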