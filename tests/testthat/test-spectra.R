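test_that("uncoupled diagonal models have zero cross-spectral structure", {
  A <- array(0, dim = c(2, 2, 2))
  A[1, 1, 1] <- 0.5; A[2, 2, 1] <- -0.3
  sp <- model_spectra(true_model(A, diag(2), 200), seq(5, 90, 5))
  expect_lt(max(sp$coherence), 1e-14)
  expect_lt(max(sp$sgc), 1e-14)
  expect_lt(max(abs(sp$instantaneous)), 1e-12)
})

test_that("Geweke decomposition identity holds on fitted models", {
  # the four terms are computed independently, so this checks the algebra
  for (sp in list(canon_fit()$spectra,
                  pair_spectra(white_ens(2000L, seed = 4L), c(1L, 2L),
                               order = 5L)$spectra,
                  pair_spectra(mixing_ens(1000L, seed = 5L), c(1L, 2L),
                               order = 10L)$spectra)) {
    lhs <- sp$sgc[, 1] + sp$sgc[, 2] + sp$instantaneous
    rhs <- -log(1 - sp$coherence[, 1])
    expect_lt(max(abs(lhs - rhs)), 1e-10)
  }
})

test_that("time-domain GC matches the spectral average and direction", {
  model <- canon_fit()$model
  fine <- seq(0.05, 99.95, by = 0.1)
  spf <- model_spectra(model, fine)
  td <- time_domain_gc(model, "2->1")
  expect_gt(td, 0)
  expect_equal(td, mean(spf$sgc[, 1]), tolerance = 0.1)
  # bottom-up truth is zero; estimate must be within noise of it
  expect_lt(time_domain_gc(model, "1->2"), 0.005)
})

test_that("higher-dimensional models expose power and coherence", {
  ens <- canon_ens()
  fit <- fit_var(ens, 1:5, order = 2L)
  sp <- model_spectra(fit, seq(5, 90, 5))
  expect_identical(dim(sp$power), c(18L, 5L))
  expect_identical(ncol(sp$coherence), 10L)
  expect_true(all(sp$coherence >= 0 & sp$coherence <= 1))
})

test_that("1/f removal recovers a constructed narrowband bump exactly", {
  fr <- seq(5, 90, 1)
  background <- 100 * fr^-1.5
  # pure power law: fitted line reproduces it to numerical precision
  res <- remove_background(background, fr)
  inb <- fr >= 5 & fr <= 30
  expect_lt(max(abs(10 * log10(background) - res$background)[inb]), 1e-8)
  # 6 dB Gaussian bump at 16 Hz on the same background
  bump_db <- 6 * exp(-(fr - 16)^2 / (2 * 2^2))
  power <- 10^((10 * log10(background) + bump_db) / 10)
  res2 <- remove_background(power, fr)
  pk <- find_peaks(res2$residual, fr)
  expect_equal(nrow(pk), 1L)
  expect_lt(abs(pk$freq - 16), 0.5)
  expect_lt(abs(pk$height - 6), 0.5)
  # clipping: residual never negative
  expect_true(all(res2$residual >= 0))
  expect_error(remove_background(power, fr, fit_band = c(5, 6)),
               "fewer than 3")
  expect_identical(eval(formals(remove_background)$fit_band), c(5, 30))
})

test_that("find_peaks handles monotone, single and multiple bumps", {
  fr <- seq(5, 90, 1)
  expect_identical(nrow(find_peaks(exp(-fr / 10), fr)), 0L)
  bump <- function(f0, h, w = 3) h * exp(-(fr - f0)^2 / (2 * w^2))
  one <- find_peaks(bump(16, 2), fr)
  expect_equal(nrow(one), 1L)
  expect_lt(abs(one$freq - 16), 0.1)
  expect_lt(abs(one$height - 2) / 2, 0.01)
  two <- find_peaks(bump(16, 2) + bump(40, 1), fr)
  expect_equal(nrow(two), 2L)
  expect_true(all(diff(two$freq) > 0))
  expect_lt(abs(two$freq[2] - 40), 0.5)
  # band edges are never peaks
  rising <- find_peaks(fr, fr)
  expect_identical(nrow(rising), 0L)
})

test_that("peak frequency is stable across orders 5-15, width is not", {
  ens <- canon_ens()
  width_at <- function(sp) {
    v <- sp$sgc[, 1]
    sum(v > max(v) / 2)  # half-height width in 1 Hz bins
  }
  peaks <- widths <- numeric(0)
  for (m in c(5L, 10L, 15L)) {
    sp <- pair_spectra(ens, c(1L, 4L), order = m, freqs = grid1())$spectra
    pk <- find_peaks(sp$sgc[, 1], grid1())
    peaks <- c(peaks, pk$freq[which.max(pk$height)])
    widths <- c(widths, width_at(sp))
  }
  expect_true(all(abs(peaks - peaks[2]) <= 1))   # same peak frequency
  expect_gte(widths[1], widths[3])               # width grows as order falls
})
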