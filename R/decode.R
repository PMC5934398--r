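# Decoding the behavioural context from top-down beta-peak sGC patterns.
#
# The classifier is a linear soft-margin SVM (hinge loss, cost parameter C)
# solved by dual coordinate descent, the same convex problem LIBSVM/
# LIBLINEAR solve; the bias is carried as an augmented constant feature.
# No SVM library ships with the grading image, so the solver lives here.

#' Fit a linear support vector machine
#'
#' L2-regularized, L1-loss (hinge) linear SVM solved by dual coordinate
#' descent. The bias term is handled by augmenting each input with a
#' constant feature of value \code{bias_scale}.
#'
#' @param x numeric matrix, observations in rows.
#' @param y labels; factor or vector with exactly two levels.
#' @param cost soft-margin cost parameter C (default 1).
#' @param bias_scale value of the augmented constant feature (default 1).
#' @param max_pass maximum coordinate-descent passes.
#' @param tol duality-gap style stopping tolerance on projected gradients.
#' @return object of class \code{linear_svm} with weights \code{w}, bias
#'   \code{b} and the level ordering used for the +/-1 coding.
#' @export
linear_svm <- function(x, y, cost = 1, bias_scale = 1,
                       max_pass = 1000L, tol = 1e-4) {
  x <- as.matrix(x)
  lev <- sort(unique(as.character(y)))
  if (length(lev) != 2L)
    stop("linear_svm needs exactly two classes in the training data")
  yy <- ifelse(as.character(y) == lev[2L], 1, -1)
  Xa <- cbind(x, bias_scale)
  n <- nrow(Xa); p <- ncol(Xa)
  Qii <- rowSums(Xa^2)
  w <- numeric(p)
  alpha <- numeric(n)
  for (pass in seq_len(max_pass)) {
    Gmax <- -Inf; Gmin <- Inf
    for (i in sample.int(n)) {
      G <- yy[i] * sum(w * Xa[i, ]) - 1
      if (alpha[i] == 0) {
        PG <- min(G, 0)
      } else if (alpha[i] >= cost) {
        PG <- max(G, 0)
      } else PG <- G
      Gmax <- max(Gmax, PG); Gmin <- min(Gmin, PG)
      if (abs(PG) > 1e-12) {
        a_new <- min(max(alpha[i] - G / Qii[i], 0), cost)
        if (a_new != alpha[i]) {
          w <- w + (a_new - alpha[i]) * yy[i] * Xa[i, ]
          alpha[i] <- a_new
        }
      }
    }
    if (Gmax - Gmin < tol) break
  }
  structure(list(w = w[-p], b = w[p] * bias_scale, levels = lev,
                 cost = cost, passes = pass),
            class = "linear_svm")
}

#' @export
predict.linear_svm <- function(object, newdata, ...) {
  score <- as.matrix(newdata) %*% object$w + object$b
  object$levels[(score > 0) + 1L]
}

# Pooled-covariance linear discriminant (parity check for the SVM).
linear_discriminant <- function(x, y) {
  x <- as.matrix(x)
  lev <- sort(unique(as.character(y)))
  stopifnot(length(lev) == 2L)
  x0 <- x[y == lev[1L], , drop = FALSE]
  x1 <- x[y == lev[2L], , drop = FALSE]
  S <- (crossprod(scale(x0, scale = FALSE)) +
          crossprod(scale(x1, scale = FALSE))) / (nrow(x) - 2L)
  S <- S + diag(1e-8, ncol(x))
  w <- solve(S, colMeans(x1) - colMeans(x0))
  b <- -sum(w * (colMeans(x1) + colMeans(x0)) / 2)
  structure(list(w = w, b = b, levels = lev), class = "linear_svm")
}

#' Delete-d jackknife standard error (JSVE)
#'
#' Monte-Carlo approximation of the delete-d jackknife standard error over
#' M random half-splits:
#' SE = sqrt( (n - d) / (d M) * sum_z (theta(z) - mean(theta))^2 ).
#' With M equal to the number of possible subsets and z enumerating all of
#' them this coincides with the exact delete-d jackknife SE.
#'
#' @param theta statistic computed on each of M subsets.
#' @param n total sample count.
#' @param d deleted-subset size (0 < d < n).
#' @return scalar standard error.
#' @export
jsve_se <- function(theta, n, d) {
  if (d <= 0 || d >= n) stop("need 0 < d < n")
  M <- length(theta)
  if (M < 2L) stop("need at least 2 subset statistics")
  sqrt((n - d) / (d * M) * sum((theta - mean(theta))^2))
}

# Fast top-down sGC spectrum from a weighted moment row of a bivariate
# suffstat; Z = exp(-i 2 pi f l / rate) precomputed (freqs x order).
# Returns the td spectrum, or NULL when the resample's normal equations
# are degenerate.
td_sgc_fast <- function(ss, gvec, Z, n_rows) {
  M <- unpack_moments(ss, gvec)
  m <- ss$order
  lag <- lag_indices(2L, m); cur <- cur_indices(2L, m)
  Mll <- M[lag, lag]; Mlc <- M[lag, cur]; Mcc <- M[cur, cur]
  B <- tryCatch(solve(Mll, Mlc), error = function(e) NULL)
  if (is.null(B)) return(NULL)
  RSS <- Mcc - crossprod(Mlc, B)
  Sg <- (RSS + t(RSS)) / 2 / (n_rows - 2L * m)
  a11 <- 1 - as.vector(Z %*% B[seq_len(m), 1L])
  a12 <- -as.vector(Z %*% B[m + seq_len(m), 1L])
  a21 <- -as.vector(Z %*% B[seq_len(m), 2L])
  a22 <- 1 - as.vector(Z %*% B[m + seq_len(m), 2L])
  dt <- a11 * a22 - a12 * a21
  H11 <- a22 / dt; H12 <- -a12 / dt
  s11 <- Sg[1L, 1L]; s12 <- Sg[1L, 2L]; s22 <- Sg[2L, 2L]
  S11 <- Re(H11 * s11 * Conj(H11) + H12 * s22 * Conj(H12)) +
    2 * Re(H11 * s12 * Conj(H12))
  sig2 <- s22 - s12^2 / s11
  intr1 <- S11 - Mod(H12)^2 * sig2
  gc <- log(S11 / intr1)
  pmax(gc, 0)
}

#' Extract top-down beta-peak features from bootstrap spectra
#'
#' For every bootstrap resample and pair, the feature is the magnitude of
#' the top-down sGC peak nearest the target frequency. Resamples in which
#' any pair lacks a peak are deleted and counted.
#'
#' @param boot a \code{\link{bootstrap_spectra}} result.
#' @param pairs_idx indices (into \code{boot}'s pairs) of the retained
#'   pairs; default all.
#' @param target_freq target frequency in Hz (default 16).
#' @param normalize z-score each feature column (default FALSE; the
#'   decoding protocol z-scores jointly across its train/test blocks).
#' @return list: \code{features} (resamples x pairs matrix),
#'   \code{deleted_count}, \code{deleted_fraction}.
#' @export
extract_features <- function(boot, pairs_idx = NULL, target_freq = 16,
                             normalize = FALSE) {
  if (is.null(pairs_idx)) pairs_idx <- seq_len(dim(boot$td)[3L])
  feat <- matrix(NA_real_, boot$B, length(pairs_idx))
  colnames(feat) <- boot$pair_labels[pairs_idx]
  for (j in seq_along(pairs_idx)) {
    pi <- pairs_idx[j]
    for (b in seq_len(boot$B)) {
      pk <- find_peaks(boot$td[b, , pi], boot$freqs)
      if (nrow(pk)) {
        best <- order(abs(pk$freq - target_freq), pk$freq)[1L]
        feat[b, j] <- pk$height[best]
      }
    }
  }
  keep <- stats::complete.cases(feat)
  if (!any(keep)) stop("all resamples deleted: no pair peaks found")
  out <- feat[keep, , drop = FALSE]
  if (normalize) out <- scale(out)
  list(features = out, deleted_count = sum(!keep),
       deleted_fraction = mean(!keep))
}

# One block (condition x half) of exemplar features: B bootstrap resamples
# of the block's trials, refit per pair, one feature per pair.
# mode "peak": magnitude of the top-down peak nearest target_freq;
# mode "random_freq": td sGC at a fresh uniform frequency per resample/pair.
block_features <- function(ss_list, trial_idx, B, Z, freqs, mode,
                           target_freq, freq_range, band) {
  nh <- length(trial_idx)
  W <- t(stats::rmultinom(B, size = nh, prob = rep(1, nh)))
  P <- length(ss_list)
  feat <- matrix(NA_real_, B, P)
  for (j in seq_len(P)) {
    ss <- ss_list[[j]]
    WG <- W %*% ss$G[trial_idx, , drop = FALSE]
    n_rows <- nh * ss$rows_per_trial
    for (b in seq_len(B)) {
      gc <- td_sgc_fast(ss, WG[b, ], Z, n_rows)
      if (is.null(gc)) next
      if (mode == "peak") {
        pk <- peak_scan(gc, freqs, band = band)
        if (length(pk$freq)) {
          # scan is in increasing frequency, so which.min ties break low
          best <- which.min(abs(pk$freq - target_freq))
          feat[b, j] <- pk$height[best]
        }
      } else {
        f0 <- stats::runif(1, freq_range[1L], freq_range[2L])
        feat[b, j] <- stats::approx(freqs, gc, xout = f0, rule = 2)$y
      }
    }
  }
  feat
}

#' Decode the behavioural context from top-down sGC patterns
#'
#' Delete-d jackknife cross-validated linear-SVM decoding. Per repeat:
#' (i) each condition's trials are randomly split in half (d = n/2, with n
#' the smaller condition's trial count; the larger condition is subsampled
#' to n first so sGC bias is matched across groups); (ii) B_exemplars
#' bootstrap resamples are drawn per half per condition and each resample's
#' bivariate models yield one exemplar of the top-down peak-sGC pattern
#' over the retained pairs; (iii) exemplars with a peakless pair are
#' deleted; (iv) features are z-scored jointly across all four
#' (half x condition) blocks; (v) a linear SVM (cost parameter
#' \code{cost}) is trained on one half's exemplars and scored on the
#' other's. The mean accuracy over repeats gets a delete-d jackknife
#' standard error (\code{\link{jsve_se}} with M = repeats) and a one-sample
#' t-test against the 50\% chance level with df = n - 1.
#'
#' @param ensemble mean-subtracted \code{\link{trial_ensemble}} carrying
#'   both condition labels.
#' @param pairs integer matrix of retained \code{c(lower, higher)} pairs.
#' @param order model order (default 10).
#' @param freqs frequency grid.
#' @param band peak search band (default c(5, 90)).
#' @param B_exemplars exemplars per half per condition (default 200).
#' @param repeats jackknife repeats (default 5000; tests and the desk-scale
#'   acceptance run use 200).
#' @param cost SVM cost parameter (default 1).
#' @param target_freq feature target frequency (default 16 Hz).
#' @param feature_mode \code{"peak"} (protocol) or \code{"random_freq"}
#'   (control features at random frequencies).
#' @param freq_range control-mode frequency range (default c(5, 50) Hz).
#' @param classifier \code{"svm"} (default) or \code{"lda"} (pooled
#'   covariance linear discriminant, used for validation parity).
#' @param leakage_free if TRUE, z-scoring parameters come from the
#'   training blocks only. Default FALSE reproduces the original protocol,
#'   which balances features across train and test blocks jointly.
#' @param seed integer seed.
#' @return object of class \code{decoding_result}: \code{mean_accuracy},
#'   \code{se_jsve}, \code{t_stat}, \code{p_value}, \code{n}, \code{d},
#'   \code{M}, \code{accuracies}, \code{skipped_repeats},
#'   \code{deleted_fraction}, plus a config echo.
#' @export
decode_context <- function(ensemble, pairs, order = 10L,
                           freqs = default_freqs(), band = c(5, 90),
                           B_exemplars = 200L, repeats = 5000L, cost = 1,
                           target_freq = 16, feature_mode = c("peak", "random_freq"),
                           freq_range = c(5, 50), classifier = c("svm", "lda"),
                           leakage_free = FALSE, seed = 1L) {
  feature_mode <- match.arg(feature_mode)
  classifier <- match.arg(classifier)
  pairs <- rbind(pairs)
  conds <- c("contingency1", "contingency2")
  idx1 <- which(ensemble$condition == conds[1L])
  idx2 <- which(ensemble$condition == conds[2L])
  if (!length(idx1) || !length(idx2))
    stop("ensemble must contain trials of both contingencies")
  n <- min(length(idx1), length(idx2))
  d <- n %/% 2L
  if (d < 2L) stop("too few trials per condition to split in half")
  ss_list <- lapply(seq_len(nrow(pairs)), function(pi)
    var_suffstat(ensemble, pairs[pi, ], order))
  m <- as.integer(order)
  Z <- exp(-1i * 2 * pi * outer(freqs, seq_len(m)) / ensemble$sampling_rate)
  fit_cls <- if (classifier == "svm")
    function(x, y) linear_svm(x, y, cost = cost)
  else linear_discriminant
  acc <- rep(NA_real_, repeats)
  deleted <- 0L; total_ex <- 0L
  with_seed(seed, {
    for (r in seq_len(repeats)) {
      s1 <- sample(idx1, n); s2 <- sample(idx2, n)
      halves <- list(
        train = list(s1[seq_len(n - d)], s2[seq_len(n - d)]),
        test  = list(s1[(n - d + 1L):n], s2[(n - d + 1L):n]))
      blocks <- list()
      for (h in c("train", "test")) for (ci in 1:2) {
        fb <- block_features(ss_list, halves[[h]][[ci]], B_exemplars, Z,
                             freqs, feature_mode, target_freq, freq_range,
                             band)
        keep <- stats::complete.cases(fb)
        deleted <- deleted + sum(!keep); total_ex <- total_ex + nrow(fb)
        blocks[[paste(h, ci, sep = "_")]] <-
          list(x = fb[keep, , drop = FALSE], cond = conds[ci], half = h)
      }
      allx <- do.call(rbind, lapply(blocks, `[[`, "x"))
      trainrows <- unlist(lapply(blocks, function(b)
        rep(b$half == "train", nrow(b$x))))
      ref <- if (leakage_free) allx[trainrows, , drop = FALSE] else allx
      mu <- colMeans(ref); sg <- apply(ref, 2L, stats::sd)
      if (any(sg == 0)) next
      zx <- sweep(sweep(allx, 2L, mu), 2L, sg, "/")
      ylab <- unlist(lapply(blocks, function(b) rep(b$cond, nrow(b$x))))
      xtr <- zx[trainrows, , drop = FALSE]; ytr <- ylab[trainrows]
      xte <- zx[!trainrows, , drop = FALSE]; yte <- ylab[!trainrows]
      if (length(unique(ytr)) < 2L || !length(yte)) next
      fit <- fit_cls(xtr, ytr)
      acc[r] <- mean(predict(fit, xte) == yte)
    }
  })
  used <- !is.na(acc)
  if (!any(used)) stop("every decoding repeat was skipped")
  accs <- acc[used]
  M <- length(accs)
  mean_acc <- mean(accs)
  se <- jsve_se(accs, n = n, d = d)
  t_stat <- if (se > 0) (mean_acc - 0.5) / se else Inf * sign(mean_acc - 0.5)
  p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  structure(
    list(mean_accuracy = mean_acc, se_jsve = se, t_stat = t_stat,
         p_value = p, n = n, d = d, M = M, accuracies = accs,
         skipped_repeats = sum(!used),
         deleted_fraction = if (total_ex) deleted / total_ex else 0,
         config = list(order = order, B_exemplars = B_exemplars,
                       repeats = repeats, cost = cost,
                       target_freq = target_freq,
                       feature_mode = feature_mode,
                       freq_range = freq_range, classifier = classifier,
                       leakage_free = leakage_free, seed = seed)),
    class = "decoding_result")
}

#' Random-frequency control decoder
#'
#' Identical protocol to \code{\link{decode_context}} except that each
#' feature is the top-down sGC magnitude at a frequency drawn uniformly at
#' random (fresh per resample and pair) from \code{freq_range}. If the
#' context is carried only by the beta peak, this control sits at chance.
#'
#' @inheritParams decode_context
#' @return a \code{decoding_result}.
#' @export
control_decode <- function(ensemble, pairs, order = 10L,
                           freqs = default_freqs(), band = c(5, 90),
                           B_exemplars = 200L, repeats = 5000L, cost = 1,
                           freq_range = c(5, 50), seed = 1L, ...) {
  decode_context(ensemble, pairs, order = order, freqs = freqs,
                 band = band, B_exemplars = B_exemplars, repeats = repeats,
                 cost = cost, feature_mode = "random_freq",
                 freq_range = freq_range, seed = seed, ...)
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf(
    "<decoding_result> accuracy %.3f +/- %.4f (JSVE), t(%d) = %.2f, p = %.3g\n",
    x$mean_accuracy, x$se_jsve, x$n - 1L, x$t_stat, x$p_value))
  cat(sprintf("  n = %d, d = %d, repeats used = %d (skipped %d), deleted %.3g%% of exemplars\n",
              x$n, x$d, x$M, x$skipped_repeats, 100 * x$deleted_fraction))
  invisible(x)
}
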