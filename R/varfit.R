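# Multi-trial AR model fitting.
#
# All estimators are pooled least squares over lag-embedded regression rows
# accumulated across trials; no regression row ever spans a trial boundary.
# Trials are short (17 samples by default) so per-trial fits are impossible
# at order 10 -- pooling across thousands of trials is what makes the model
# identifiable. Internally everything is expressed through moment matrices
# of the embedded variable u = (x_t, x_{t-1}, .., x_{t-m}) per channel,
# which makes bootstrap resampling (reweight per-trial moments) and trial
# permutation (reorder one channel's embedded rows) cheap.

# Lag-embed one channel: matrix with n_trials*(T-m) rows (trial-major
# blocks) and m+1 columns (x_t, x_{t-1}, ..., x_{t-m}).
embed_channel <- function(ensemble, channel, order) {
  x <- ensemble$data[, channel, , drop = TRUE]
  if (is.null(dim(x))) x <- matrix(x, nrow = n_trials(ensemble))
  ns <- ncol(x)
  if (ns <= order)
    stop(sprintf("trials have %d samples; need more than the model order %d",
                 ns, order))
  rows <- ns - order
  E <- matrix(0, nrow(x) * rows, order + 1L)
  for (j in 0:order)
    E[, j + 1L] <- as.vector(t(x[, (order + 1L - j):(ns - j), drop = FALSE]))
  E
}

# Joint embedding for a channel subset: columns grouped by channel,
# each group = (current, lag 1, .., lag m).
embed_channels <- function(ensemble, channels, order) {
  do.call(cbind, lapply(channels, embed_channel,
                        ensemble = ensemble, order = order))
}

cur_indices <- function(k, m) seq(1L, by = m + 1L, length.out = k)
lag_indices <- function(k, m)
  as.vector(vapply(seq_len(k), function(c) (c - 1L) * (m + 1L) + 1L + seq_len(m),
                   integer(m)))

#' Per-trial sufficient statistics for a channel subset
#'
#' Accumulates, for every trial, the cross-moment matrix of the lag-embedded
#' variables of the given channels. Any reweighting of trials (bootstrap
#' resample, subset, full fit) then reduces to a single matrix product, so
#' thousands of resample fits cost one BLAS call plus small solves.
#'
#' @param ensemble a mean-subtracted \code{\link{trial_ensemble}}.
#' @param channels integer channel indices (order defines the model's
#'   channel order; for ordered pairs use \code{c(target, source)}).
#' @param order model order m.
#' @return an object of class \code{var_suffstat}.
#' @export
var_suffstat <- function(ensemble, channels, order) {
  k <- length(channels)
  m <- as.integer(order)
  E <- embed_channels(ensemble, channels, m)
  D <- ncol(E)
  rows_per_trial <- nrow(E) / n_trials(ensemble)
  idx <- which(upper.tri(matrix(0, D, D), diag = TRUE), arr.ind = TRUE)
  grp <- rep(seq_len(n_trials(ensemble)), each = rows_per_trial)
  P <- E[, idx[, 1L], drop = FALSE] * E[, idx[, 2L], drop = FALSE]
  G <- rowsum(P, grp, reorder = FALSE)
  structure(
    list(G = G, tri = idx, D = D, k = k, order = m,
         rows_per_trial = rows_per_trial,
         n_trials = n_trials(ensemble),
         samples_per_trial = dim(ensemble$data)[3L],
         sampling_rate = ensemble$sampling_rate,
         channels = channels,
         channel_labels = ensemble$channel_labels[channels]),
    class = "var_suffstat")
}

# Reassemble a symmetric moment matrix from one (weighted) row of G.
unpack_moments <- function(ss, gvec) {
  M <- matrix(0, ss$D, ss$D)
  M[ss$tri] <- gvec
  M[ss$tri[, c(2L, 1L)]] <- gvec
  M
}

# Fit the pooled VAR from a moment matrix. n_rows = effective regression
# row count behind M (sum of trial weights times rows per trial).
fit_from_moments <- function(M, k, m, n_rows, sampling_rate,
                             samples_per_trial, n_trials,
                             channel_labels = NULL) {
  cur <- cur_indices(k, m)
  lag <- lag_indices(k, m)
  n_reg <- k * m
  if (n_rows <= n_reg + k)
    stop("too few pooled regression rows for the requested order")
  Mll <- M[lag, lag, drop = FALSE]
  Mlc <- M[lag, cur, drop = FALSE]
  Mcc <- M[cur, cur, drop = FALSE]
  rc <- rcond(Mll)
  if (!is.finite(rc) || rc < 1e-13)
    stop(sprintf(
      "ill-conditioned normal equations (reciprocal condition number %.3g)", rc))
  B <- solve(Mll, Mlc)                       # (k*m) x k coefficient block
  RSS <- Mcc - crossprod(Mlc, B)
  Sigma <- (RSS + t(RSS)) / 2 / (n_rows - n_reg)
  A <- array(0, dim = c(k, k, m))
  for (j in seq_len(k)) for (l in seq_len(m))
    A[, j, l] <- B[(j - 1L) * m + l, ]
  # restricted (single-channel) models from the same moments
  restricted <- numeric(k)
  for (c in seq_len(k)) {
    ci <- (c - 1L) * (m + 1L) + 1L
    li <- ci + seq_len(m)
    b <- solve(M[li, li, drop = FALSE], M[li, ci])
    restricted[c] <- (M[ci, ci] - sum(M[li, ci] * b)) / (n_rows - m)
  }
  if (!is.null(channel_labels)) names(restricted) <- channel_labels
  structure(
    list(order = m, A = A, Sigma = Sigma, restricted_var = restricted,
         n_trials = n_trials, samples_per_trial = samples_per_trial,
         sampling_rate = sampling_rate, n_rows = n_rows,
         channel_labels = channel_labels),
    class = "var_model")
}

# Fit from suffstats under trial weights (NULL = all ones).
fit_weighted <- function(ss, weights = NULL) {
  g <- if (is.null(weights)) colSums(ss$G) else as.vector(weights %*% ss$G)
  n_rows <- ss$rows_per_trial *
    if (is.null(weights)) ss$n_trials else sum(weights)
  fit_from_moments(unpack_moments(ss, g), ss$k, ss$order, n_rows,
                   ss$sampling_rate, ss$samples_per_trial,
                   if (is.null(weights)) ss$n_trials else sum(weights),
                   ss$channel_labels)
}

#' Fit a pooled multi-trial AR model
#'
#' Solves the pooled least-squares normal equations formed by accumulating
#' lag moments across trials (regression rows never span a trial boundary).
#' The residual covariance is the pooled residual covariance; single-channel
#' restricted models are fitted from the same moments and their residual
#' variances stored for time-domain causality.
#'
#' @param ensemble a \code{\link{trial_ensemble}} whose ensemble mean has
#'   been subtracted (see \code{\link{subtract_ensemble_mean}}).
#' @param channels integer channel indices defining the model's channels.
#' @param order model order m (default 10, the AIC-selected value for this
#'   class of data).
#' @return an object of class \code{var_model} with elements \code{A}
#'   (channels x channels x order coefficient array), \code{Sigma}
#'   (residual covariance), \code{restricted_var} (per-channel restricted
#'   residual variances), and fit metadata.
#' @export
fit_var <- function(ensemble, channels = seq_along(ensemble$channel_labels),
                    order = 10L) {
  ss <- var_suffstat(ensemble, channels, order)
  n_reg <- ss$k * ss$order
  if (ss$n_trials * ss$rows_per_trial < 10L * n_reg)
    stop(sprintf(
      "only %d pooled regression rows for %d regressors; need >= 10x as many",
      ss$n_trials * ss$rows_per_trial, n_reg))
  fit_weighted(ss)
}

#' @export
print.var_model <- function(x, ...) {
  k <- dim(x$A)[1L]
  cat(sprintf("<var_model> %d channels, order %d, fitted on %d trials x %d samples\n",
              k, x$order, x$n_trials, x$samples_per_trial))
  invisible(x)
}

#' Model-order selection by the Akaike Information Criterion
#'
#' Scans candidate orders and returns the AIC minimizer together with the
#' full criterion curve: AIC(m) = N * ln det(Sigma_ML(m)) + 2 m k^2. All
#' candidate orders are fitted on the same regression rows (the first
#' max(orders) samples of every trial are dropped throughout), so the
#' criterion values are comparable across orders.
#'
#' @param ensemble a mean-subtracted \code{\link{trial_ensemble}}.
#' @param channels channel indices.
#' @param orders candidate orders (default \code{5:15}, the scan range used
#'   to confirm peak-frequency robustness).
#' @return list with \code{order} (selected), \code{aic} (named curve).
#' @export
select_order_aic <- function(ensemble,
                             channels = seq_along(ensemble$channel_labels),
                             orders = 5:15) {
  k <- length(channels)
  mx <- max(orders)
  E <- embed_channels(ensemble, channels, mx)
  M <- crossprod(E)
  N <- nrow(E)
  cur <- cur_indices(k, mx)
  aic <- vapply(orders, function(m) {
    lag <- as.vector(vapply(seq_len(k), function(c)
      (c - 1L) * (mx + 1L) + 1L + seq_len(m), integer(m)))
    Mll <- M[lag, lag, drop = FALSE]
    Mlc <- M[lag, cur, drop = FALSE]
    B <- solve(Mll, Mlc)
    sig_ml <- (M[cur, cur] - crossprod(Mlc, B)) / N
    N * as.numeric(determinant(sig_ml, logarithm = TRUE)$modulus) +
      2 * m * k^2
  }, numeric(1))
  names(aic) <- orders
  list(order = orders[which.min(aic)], aic = aic)
}
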