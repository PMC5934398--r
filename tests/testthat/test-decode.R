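# Decoder components; full-protocol behaviour is covered in
# test-acceptance.R at the stated scale, so these stay small.

test_that("the in-package linear SVM solves separable problems", {
  set.seed(21)
  x <- rbind(matrix(rnorm(100, mean = -2), 50, 2),
             matrix(rnorm(100, mean = 2), 50, 2))
  y <- rep(c("a", "b"), each = 50)
  fit <- linear_svm(x, y, cost = 1)
  expect_identical(as.character(predict(fit, x)), y)
  # agrees with the pooled-covariance discriminant on easy data
  lda <- betaflow:::linear_discriminant(x, y)
  expect_gt(mean(predict(lda, x) == predict(fit, x)), 0.95)
  expect_error(linear_svm(x, rep("a", 100)), "two classes")
})

test_that("z-scoring makes the SVM invariant to common affine rescaling", {
  set.seed(22)
  x <- matrix(rnorm(120), 60, 2)
  y <- rep(c("a", "b"), 30)
  zx <- scale(x)
  zx2 <- scale(x * 7.3 + 11)   # common affine map of all raw features
  expect_equal(unclass(zx), unclass(zx2), ignore_attr = TRUE)
})

test_that("jsve_se matches the exhaustive delete-d jackknife", {
  # n = 4, d = 2: all 6 half-subsets, statistic = subset mean.
  vals <- c(3, 1, 4, 1.5)
  subsets <- combn(4, 2)
  theta <- apply(subsets, 2, function(z) mean(vals[-z]))  # keep n - d
  # Eq. 6 computed from first principles with the full enumeration
  se_exact <- sqrt((4 - 2) / (2 * choose(4, 2)) *
                     sum((theta - mean(theta))^2))
  expect_equal(jsve_se(theta, n = 4, d = 2), se_exact)
  expect_equal(jsve_se(rep(0.7, 10), n = 10, d = 5), 0)
  expect_error(jsve_se(theta, n = 4, d = 4), "0 < d < n")
  expect_error(jsve_se(0.5, n = 4, d = 2), "at least 2")
})

test_that("extract_features picks the nearest peak and counts deletions", {
  fr <- seq(5, 90, 1)
  mk_spec <- function(f0, h) h * exp(-(fr - f0)^2 / 8)
  td <- array(0, dim = c(3, length(fr), 2))
  td[1, , 1] <- mk_spec(16, 2); td[1, , 2] <- mk_spec(16, 1)
  td[2, , 1] <- mk_spec(14, 3); td[2, , 2] <- mk_spec(40, 2)
  td[3, , 1] <- exp(-fr / 10)   # monotone: no peak -> resample deleted
  td[3, , 2] <- mk_spec(16, 1)
  boot <- structure(list(td = td, freqs = fr, B = 3L,
                         pair_labels = c("H1->L1", "H2->L2")),
                    class = "boot_spectra")
  fs <- extract_features(boot, target_freq = 16)
  expect_identical(fs$deleted_count, 1L)
  expect_equal(fs$deleted_fraction, 1 / 3)
  expect_equal(dim(fs$features), c(2L, 2L))
  expect_equal(unname(fs$features[1, 1]), 2, tolerance = 1e-6)
  expect_equal(unname(fs$features[2, 2]), 2, tolerance = 1e-6)
  td[, , 1] <- matrix(exp(-fr / 10), 3, length(fr), byrow = TRUE)
  boot$td <- td
  expect_error(extract_features(boot), "all resamples deleted")
})

test_that("decode_context is deterministic and reports its bookkeeping", {
  spec <- canonical_conditions(trials_per_condition = 300L, contrast = 0.3,
                               seed = 33L)
  ens <- subtract_ensemble_mean(simulate_trials(spec))
  pairs <- area_pairs(ens)[c(1L, 5L), ]
  d1 <- decode_context(ens, pairs, B_exemplars = 40L, repeats = 10L,
                       seed = 5L)
  d2 <- decode_context(ens, pairs, B_exemplars = 40L, repeats = 10L,
                       seed = 5L)
  expect_identical(d1$accuracies, d2$accuracies)
  expect_identical(d1$n, 300L)
  expect_identical(d1$d, 150L)
  expect_true(d1$mean_accuracy >= 0 && d1$mean_accuracy <= 1)
  expect_gte(d1$se_jsve, 0)
  # large contrast at this size already decodes well
  expect_gt(d1$mean_accuracy, 0.6)
})

test_that("svm and discriminant validation runs agree", {
  spec <- canonical_conditions(trials_per_condition = 300L, contrast = 0.3,
                               seed = 34L)
  ens <- subtract_ensemble_mean(simulate_trials(spec))
  pairs <- area_pairs(ens)[c(1L, 5L), ]
  a_svm <- decode_context(ens, pairs, B_exemplars = 40L, repeats = 25L,
                          seed = 6L)$mean_accuracy
  a_lda <- decode_context(ens, pairs, B_exemplars = 40L, repeats = 25L,
                          seed = 6L, classifier = "lda")$mean_accuracy
  expect_lt(abs(a_svm - a_lda), 0.05)
})

test_that("decoding tracks the coupling contrast and its location", {
  # monotonicity in the contrast (scaled-down: 3 seeds, contrasts 0/0.3)
  pairs_of <- function(ens) area_pairs(ens)[c(1L, 5L), ]
  acc_at <- function(contrast, seed) {
    ens <- subtract_ensemble_mean(simulate_trials(canonical_conditions(
      trials_per_condition = 300L, contrast = contrast, seed = seed)))
    decode_context(ens, pairs_of(ens), B_exemplars = 40L, repeats = 25L,
                   seed = seed)$mean_accuracy
  }
  ok <- 0L
  for (s in 1:3) ok <- ok + (acc_at(0.3, 50L + s) >= acc_at(0, 60L + s))
  expect_gte(ok, 2L)

  # specificity: a bottom-up coupling contrast carries no peak-feature
  # signal (conditions built from two separately simulated networks)
  bu_net <- function(coef, seed) {
    base <- network_spec(
      2, 2, osc_freq = 16, osc_damping = 0.9,
      coupling = data.frame(from = c("H1", "L1"), to = c("L1", "H1"),
                            lag = 1L, coef = c(0.2, coef)))
    simulate_trials(condition_pair_spec(base, trials_per_condition = 150L,
                                        seed = seed))
  }
  e1 <- bu_net(0.26, 71L); e2 <- bu_net(0.14, 72L)
  joined <- trial_ensemble(
    abind_trials(e1$data, e2$data), e1$sampling_rate, e1$channel_labels,
    e1$area, rep(c("contingency1", "contingency2"),
                 c(dim(e1$data)[1], dim(e2$data)[1])))
  ens <- subtract_ensemble_mean(joined)
  res <- decode_context(ens, area_pairs(ens)[1, , drop = FALSE],
                        B_exemplars = 40L, repeats = 50L, seed = 9L)
  expect_gt(res$mean_accuracy, 0.35)
  expect_lt(res$mean_accuracy, 0.65)
})
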