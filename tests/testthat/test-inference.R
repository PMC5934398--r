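test_that("bootstrap spectra are reproducible and centred on the full fit", {
  ens <- canon_ens()
  pair <- matrix(c(1L, 4L), 1)
  b1 <- bootstrap_spectra(ens, pair, order = 10L, freqs = grid1(),
                          B = 2L, seed = 9L)
  b2 <- bootstrap_spectra(ens, pair, order = 10L, freqs = grid1(),
                          B = 2L, seed = 9L)
  expect_identical(b1$td, b2$td)
  expect_error(bootstrap_spectra(ens, pair, B = 1L), "B >= 2")

  # bootstrap mean within 3 bootstrap SE of the all-trials estimate
  boot <- canon_boot()
  full_td <- boot$full[[1]]$sgc[, 1]
  bm <- colMeans(boot$td[, , 1])
  se <- apply(boot$td[, , 1], 2, sd)
  expect_true(all(abs(bm - full_td) <= 3 * pmax(se, 1e-12)))
  expect_identical(eval(formals(bootstrap_spectra)$B), 1000L)
})

test_that("directional asymmetry flags the true peak and nothing when null", {
  boot <- canon_boot()
  td <- apply(boot$td, c(1, 2), mean)
  bu <- apply(boot$bu, c(1, 2), mean)
  # identical inputs: difference identically zero, nothing significant
  null <- directional_asymmetry(td, td, n = boot$n, freqs = grid1())
  expect_true(all(null$mean_diff == 0))
  expect_false(any(null$significant))

  asym <- directional_asymmetry(td, bu, n = boot$n, freqs = grid1())
  truth_peak <- grid1()[which.max(canon_truth()$sgc[, 1])]
  expect_true(length(asym$sig_freqs) > 0)
  expect_true(truth_peak %in% asym$sig_freqs)
  # t multiplier at alpha 0.001 two-tailed is the 99.95th percentile
  expect_equal(asym$t_mult, qt(0.9995, boot$n - 1))
  # omnibus SE dominates every pointwise SE (family-wise correction)
  expect_true(all(asym$se_omnibus >= asym$se_pointwise))
  expect_error(directional_asymmetry(td[1:10, ], bu, n = boot$n), "shape")
})

test_that("null threshold is scale-free and guards its quantile", {
  ens <- null_osc_ens(ntr = 300L, seed = 31L)
  pair <- area_pairs(ens)
  thr <- peak_null_threshold(ens, pair, order = 10L, freqs = grid1(),
                             n_null = 50L, seed = 13L)
  # rescaling channel amplitudes leaves sGC untouched: identical nulls
  scaled <- ens
  scaled$data <- scaled$data * 37.5
  thr2 <- peak_null_threshold(scaled, pair, order = 10L, freqs = grid1(),
                              n_null = 50L, seed = 13L)
  expect_equal(thr$null_max, thr2$null_max, tolerance = 1e-10)
  expect_error(peak_null_threshold(ens, pair, n_null = 10L), "quantile")
  expect_identical(eval(formals(peak_null_threshold)$n_null), 1000L)
  expect_identical(eval(formals(peak_null_threshold)$q), 0.95)
})

test_that("peak tables feed consistent-pair selection", {
  # all pairs peak at exactly 16 Hz in every bootstrap: all retained,
  # CI collapses onto 16
  pt <- data.frame(pair = rep(c("a", "b", "c"), each = 10),
                   pair_index = rep(1:3, each = 10),
                   boot = rep(1:10, 3), freq = 16, height = 1,
                   significant = TRUE)
  sel <- select_consistent_pairs(pt, target = 16, n = 1000L)
  expect_identical(sel$retained, 1:3)
  expect_equal(sel$ci, c(16, 16))

  # 8 tight pairs at 16 Hz vs 4 pairs peaking anywhere in 5-50 Hz:
  # exactly the 8 retained in >= 90% of 20 seeds
  hits <- 0L
  for (s in 1:20) {
    set.seed(400L + s)
    B <- 500L
    tight <- data.frame(pair_index = rep(1:8, each = B),
                        boot = rep(1:B, 8),
                        freq = 16 + rnorm(8 * B, sd = 0.5))
    loose <- data.frame(pair_index = rep(9:12, each = B),
                        boot = rep(1:B, 4),
                        freq = runif(4 * B, 5, 50))
    pt <- rbind(tight, loose)
    pt$pair <- paste0("p", pt$pair_index)
    pt$height <- 1; pt$significant <- TRUE
    sel <- select_consistent_pairs(pt, target = 16, n = 5000L)
    hits <- hits + identical(sort(sel$retained), 1:8)
  }
  expect_gte(hits, 18L)

  # a pair with no peaks anywhere is excluded with a warning
  expect_warning(
    select_consistent_pairs(pt[pt$pair_index != 3, ], target = 16,
                            n = 5000L, expected_pairs = 1:12),
    "excluded")
})

test_that("nearest-peak selection breaks ties toward the lower frequency", {
  pt <- data.frame(pair = "a", pair_index = 1L, boot = c(1L, 1L),
                   freq = c(14, 18), height = 1, significant = TRUE)
  np <- betaflow:::nearest_peaks(pt, target = 16)
  expect_equal(np$freq, 14)
})

test_that("modal peak frequency lands on the dominant concentration", {
  set.seed(6)
  pt <- data.frame(pair = "a", pair_index = 1L, boot = seq_len(500),
                   freq = c(rnorm(400, 16, 1.5), runif(100, 5, 90)),
                   height = 1, significant = TRUE)
  mf <- modal_peak_frequency(pt)
  expect_lt(abs(mf$mode - 16), 2)
})

test_that("time-reversal test rejects empty bands and keeps true coupling", {
  ens <- coupled_pair_ens(ntr = 800L, seed = 77L)
  expect_error(time_reversal_test(ens, area_pairs(ens), band = c(91, 95)),
               "band")
  res <- time_reversal_test(ens, area_pairs(ens), band = c(10, 22),
                            seed = 2L)
  expect_true(res$genuine)
  # the fidelity ("bins") unit is available and reports df = bins - 1
  res_bins <- time_reversal_test(ens, area_pairs(ens), band = c(10, 22),
                                 unit = "bins")
  expect_identical(res_bins$df, 12)
})

test_that("coherence-sGC correlation behaves at its edge cases", {
  expect_equal(coherence_gc_correlation(c(1, 2, 3), c(2, 4, 6))$r_squared, 1)
  expect_error(coherence_gc_correlation(c(1, 1, 1), c(1, 2, 3)),
               "zero variance")
  expect_error(coherence_gc_correlation(c(1, 2), c(1, 2)), "3 pairs")

  # independent pair values: |R| below its permutation null 95% quantile
  # in >= 90% of 50 seeds
  hits <- 0L
  for (s in 1:50) {
    set.seed(500L + s)
    x <- rnorm(20); y <- rnorm(20)
    r <- abs(coherence_gc_correlation(x, y)$r)
    null_q <- quantile(replicate(199, abs(cor(sample(x), y))), 0.95)
    hits <- hits + (r < null_q)
  }
  expect_gte(hits, 45L)

  # normalized variant standardizes per pair over bootstraps
  set.seed(8)
  sgc <- matrix(rnorm(200, 5), 50, 4)
  coh <- sgc * 0.5 + matrix(rnorm(200, sd = 0.1), 50, 4)
  rn <- coherence_gc_correlation(sgc, coh, normalized = TRUE)
  expect_gt(rn$r_squared, 0.5)
  expect_true(rn$normalized)
})

test_that("top-down sGC drives both coherence and correlation asymmetry", {
  # across the canonical pairs, coherence at the peak frequency is
  # explained far better by top-down than by bottom-up sGC
  boot <- canon_boot()
  fi <- which.min(abs(grid1() - 16))
  td_r2 <- coherence_gc_correlation(boot$td[, fi, ],
                                    boot$coherence[, fi, ])$r_squared
  bu_r2 <- coherence_gc_correlation(boot$bu[, fi, ],
                                    boot$coherence[, fi, ])$r_squared
  expect_gt(td_r2, bu_r2)
})
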