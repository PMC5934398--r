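# Parametric spectra from fitted (or true) AR models.
#
# The spectral matrix is S(f) = H(f) Sigma H(f)*, with transfer function
# H(f) = (I - sum_l A_l e^{-i 2 pi f l / rate})^{-1}. Directed spectral
# Granger causality follows Geweke's bivariate decomposition: the log-ratio
# of total power of the target to its intrinsic power (the part not
# predicted by the source). Together with the closed-form instantaneous
# term, the two directed terms sum exactly to the total interdependence
# -ln(1 - coherence); the package computes all four independently so that
# identity is a genuine numerical check, not a tautology.

default_freqs <- function(from = 5, to = 90, by = 1) seq(from, to, by = by)

#' Spectra implied by an AR model
#'
#' Computes power, coherence and (for bivariate models) directed spectral
#' Granger causality and instantaneous causality on a frequency grid, from
#' the model's coefficients and residual covariance. Works identically for
#' fitted models and for ground-truth coefficient sets wrapped via
#' \code{\link{true_model}}.
#'
#' @param model a \code{var_model} (fitted or true).
#' @param freqs frequency grid in Hz, strictly inside (0, Nyquist);
#'   default 5..90 Hz in 1 Hz steps.
#' @return an object of class \code{spectrum_set}: \code{freqs};
#'   \code{power} (frequencies x channels); \code{coherence} (frequencies x
#'   unordered pairs); for bivariate models also \code{sgc} (frequencies x
#'   2, columns \code{"2->1"} and \code{"1->2"}) and \code{instantaneous}.
#' @export
model_spectra <- function(model, freqs = default_freqs()) {
  fs <- model$sampling_rate
  if (any(freqs <= 0) || any(freqs >= fs / 2))
    stop("frequency grid must lie strictly inside (0, Nyquist)")
  k <- dim(model$A)[1L]
  if (k == 2L) return(bivariate_spectra(model, freqs))
  p <- dim(model$A)[3L]
  nf <- length(freqs)
  power <- matrix(0, nf, k)
  pairs <- utils::combn(k, 2L)
  coh <- matrix(0, nf, ncol(pairs))
  for (fi in seq_len(nf)) {
    z <- exp(-1i * 2 * pi * freqs[fi] * seq_len(p) / fs)
    Af <- diag(k) + 0i
    for (l in seq_len(p)) Af <- Af - model$A[, , l] * z[l]
    H <- tryCatch(solve(Af), error = function(e)
      stop(sprintf("transfer function singular at %.3f Hz (pole on grid)",
                   freqs[fi])))
    S <- H %*% model$Sigma %*% Conj(t(H))
    power[fi, ] <- Re(diag(S))
    for (pc in seq_len(ncol(pairs)))
      coh[fi, pc] <- Mod(S[pairs[1L, pc], pairs[2L, pc]])^2 /
        (Re(S[pairs[1L, pc], pairs[1L, pc]]) * Re(S[pairs[2L, pc], pairs[2L, pc]]))
  }
  labs <- model$channel_labels %||% paste0("ch", seq_len(k))
  colnames(power) <- labs
  colnames(coh) <- apply(pairs, 2L, function(ij)
    paste(labs[ij[1L]], labs[ij[2L]], sep = ":"))
  structure(list(freqs = freqs, power = power, coherence = coh,
                 sgc = NULL, instantaneous = NULL),
            class = "spectrum_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Fully vectorized bivariate case (the workhorse: every ordered pair is
# analysed through its own bivariate model).
bivariate_spectra <- function(model, freqs) {
  fs <- model$sampling_rate
  A <- model$A; Sg <- model$Sigma
  p <- dim(A)[3L]
  Z <- exp(-1i * 2 * pi * outer(freqs, seq_len(p)) / fs)   # F x p
  a11 <- 1 - as.vector(Z %*% A[1, 1, ]); a12 <- -as.vector(Z %*% A[1, 2, ])
  a21 <- -as.vector(Z %*% A[2, 1, ]);    a22 <- 1 - as.vector(Z %*% A[2, 2, ])
  dt <- a11 * a22 - a12 * a21
  if (any(Mod(dt) < 1e-300))
    stop("transfer function singular on the frequency grid (pole on grid)")
  H11 <- a22 / dt; H12 <- -a12 / dt; H21 <- -a21 / dt; H22 <- a11 / dt
  s11 <- Sg[1, 1]; s12 <- Sg[1, 2]; s22 <- Sg[2, 2]
  S11 <- Re(H11 * s11 * Conj(H11) + H12 * s22 * Conj(H12)) +
    2 * Re(H11 * s12 * Conj(H12))
  S22 <- Re(H21 * s11 * Conj(H21) + H22 * s22 * Conj(H22)) +
    2 * Re(H21 * s12 * Conj(H22))
  S12 <- H11 * s11 * Conj(H21) + H11 * s12 * Conj(H22) +
    H12 * s12 * Conj(H21) + H12 * s22 * Conj(H22)
  coh <- Mod(S12)^2 / (S11 * S22)
  sig2 <- s22 - s12^2 / s11       # source-2 innovations orthogonalized on 1
  sig1 <- s11 - s12^2 / s22
  intr1 <- S11 - Mod(H12)^2 * sig2   # intrinsic power of channel 1
  intr2 <- S22 - Mod(H21)^2 * sig1
  gc21 <- log(S11 / intr1)
  gc12 <- log(S22 / intr2)
  detS <- S11 * S22 - Mod(S12)^2
  inst <- log(intr1 * intr2 / detS)
  for (v in list(gc21, gc12)) {
    if (any(v < -1e-10))
      stop("negative spectral GC beyond tolerance: numerical factorization error")
  }
  gc21 <- pmax(gc21, 0); gc12 <- pmax(gc12, 0)
  labs <- model$channel_labels %||% c("ch1", "ch2")
  power <- cbind(S11, S22); colnames(power) <- labs
  sgc <- cbind(gc21, gc12)
  colnames(sgc) <- c(paste0(labs[2L], "->", labs[1L]),
                     paste0(labs[1L], "->", labs[2L]))
  structure(list(freqs = freqs, power = power,
                 coherence = matrix(coh, ncol = 1,
                                    dimnames = list(NULL, paste(labs, collapse = ":"))),
                 sgc = sgc, instantaneous = inst),
            class = "spectrum_set")
}

#' Wrap ground-truth coefficients as a model object
#'
#' @param A coefficient array channels x channels x order.
#' @param Sigma innovation covariance.
#' @param sampling_rate Hz.
#' @param channel_labels optional channel names.
#' @return a \code{var_model} usable with \code{\link{model_spectra}}.
#' @export
true_model <- function(A, Sigma, sampling_rate, channel_labels = NULL) {
  structure(list(order = dim(A)[3L], A = A, Sigma = Sigma,
                 restricted_var = NULL, n_trials = NA_integer_,
                 samples_per_trial = NA_integer_,
                 sampling_rate = sampling_rate,
                 channel_labels = channel_labels),
            class = "var_model")
}

#' Closed-form bivariate truth for one directed pair of a network
#'
#' Extracts the exact bivariate subsystem (target, source) of a
#' \code{\link{network_spec}} whose innovations are diagonal and whose
#' target receives input only from the source: in that case the pair is a
#' closed VAR and its Geweke spectra are exact. Used as the oracle for
#' estimator checks.
#'
#' @param spec a \code{\link{network_spec}}.
#' @param target,source channel labels (target first, so top-down truth is
#'   \code{source -> target} with a lower-area target).
#' @return a bivariate \code{var_model} of the true subsystem.
#' @export
true_pair_model <- function(spec, target, source) {
  net <- build_var(spec)
  idx <- match(c(target, source), spec$channel_labels)
  others <- setdiff(seq_along(spec$channel_labels), idx)
  if (any(net$A[idx[1L], others, ] != 0) || any(net$A[idx[2L], others, ] != 0) ||
      any(net$A[idx[2L], idx[1L], ] != 0) ||
      any(net$Sigma[idx, others] != 0))
    warning("pair subsystem is not closed; bivariate truth is approximate")
  A2 <- net$A[idx, idx, , drop = FALSE]
  S2 <- net$Sigma[idx, idx]
  true_model(A2, S2, spec$sampling_rate, spec$channel_labels[idx])
}

#' Time-domain Granger causality from a fitted bivariate model
#'
#' The log-ratio of the restricted (single-channel) residual variance of the
#' target to its unrestricted residual variance in the bivariate model.
#' Non-negative up to estimation noise; by Geweke's integral identity it
#' equals the average of the spectral measure over (0, Nyquist).
#'
#' @param model a fitted bivariate \code{var_model} (needs
#'   \code{restricted_var}).
#' @param direction \code{"2->1"} (channel 2 drives channel 1) or
#'   \code{"1->2"}.
#' @return scalar time-domain GC.
#' @export
time_domain_gc <- function(model, direction = c("2->1", "1->2")) {
  direction <- match.arg(direction)
  if (is.null(model$restricted_var))
    stop("model carries no restricted fits (was it fitted from data?)")
  target <- if (direction == "2->1") 1L else 2L
  rv <- model$restricted_var[target]
  uv <- model$Sigma[target, target]
  if (rv <= 0 || uv <= 0)
    stop("non-positive residual variance: degenerate data")
  unname(log(rv / uv))
}

#' Remove the 1/f aperiodic background from a power spectrum
#'
#' Converts power to dB, fits a line in (log10 frequency, dB) over the fit
#' band by iteratively reweighted least squares with Welsch weights
#' w(u) = exp(-u^2), u = r / (c s), c = 2.985, s the normalized median
#' absolute deviation of the residuals, then subtracts the fitted
#' background (evaluated over the whole grid) and clips negative residuals
#' to zero. A narrow fit band centred on the oscillation of interest keeps
#' other spectral concentrations from biasing the line.
#'
#' @param power positive power values on \code{freqs}.
#' @param freqs frequency grid in Hz.
#' @param fit_band band used for the robust fit; default c(5, 30) Hz.
#' @param space \code{"db"} (default) subtracts in decibel space;
#'   \code{"linear"} subtracts the back-transformed background from raw
#'   power instead.
#' @param c_welsch Welsch tuning constant (default 2.985, the conventional
#'   95\%-efficiency value).
#' @param max_iter IRLS iteration cap.
#' @return list with \code{residual} (background-removed spectrum, clipped
#'   at zero; dB or linear per \code{space}), \code{background} (fitted
#'   background on the full grid, same space), \code{coef} (intercept,
#'   slope in dB per decade), \code{iterations}, \code{converged}.
#' @export
remove_background <- function(power, freqs, fit_band = c(5, 30),
                              space = c("db", "linear"),
                              c_welsch = 2.985, max_iter = 100L) {
  space <- match.arg(space)
  if (any(power <= 0)) stop("power must be strictly positive")
  inb <- freqs >= fit_band[1L] & freqs <= fit_band[2L]
  if (sum(inb) < 3L)
    stop("fewer than 3 frequencies inside the fit band")
  y <- 10 * log10(power)
  x <- log10(freqs)
  X <- cbind(1, x[inb]); yb <- y[inb]
  beta <- stats::coef(stats::lm.fit(X, yb))
  converged <- FALSE; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    r <- yb - X %*% beta
    s <- stats::mad(r)
    if (s < 1e-12) { converged <- TRUE; break }
    u <- r / (c_welsch * s)
    w <- exp(-u^2)
    beta_new <- stats::coef(stats::lm.wfit(X, yb, as.vector(w)))
    if (max(abs(beta_new - beta)) < 1e-10) {
      beta <- beta_new; converged <- TRUE; break
    }
    beta <- beta_new
  }
  if (!converged)
    warning("robust background fit did not converge; using last iterate")
  bg_db <- beta[1L] + beta[2L] * x
  if (space == "db") {
    resid <- pmax(y - bg_db, 0)
    background <- bg_db
  } else {
    resid <- pmax(power - 10^(bg_db / 10), 0)
    background <- 10^(bg_db / 10)
  }
  list(residual = resid, background = background,
       coef = stats::setNames(as.numeric(beta), c("intercept", "slope")),
       iterations = it, converged = converged)
}

#' Locate spectral peaks
#'
#' Local maxima found by sign change of the (optionally smoothed) first
#' difference, with position and height refined by quadratic interpolation
#' through the three points around each maximum. Band-edge samples are
#' never returned as peaks.
#'
#' @param values spectrum values on \code{freqs}.
#' @param freqs frequency grid (Hz), uniformly spaced.
#' @param band analysis band; default c(5, 90) Hz.
#' @param smooth width (in grid points, odd) of a moving-average smoother
#'   applied to the first difference before the sign-change scan; 1 = none.
#' @return data frame with columns \code{freq} and \code{height}, ordered
#'   by increasing frequency (zero rows when the spectrum is monotone).
#' @export
find_peaks <- function(values, freqs, band = c(5, 90), smooth = 1L) {
  pk <- peak_scan(values, freqs, band, smooth)
  data.frame(freq = pk$freq, height = pk$height)
}

# Allocation-light peak scanner (list of vectors); hot path of the decoder.
peak_scan <- function(values, freqs, band = c(5, 90), smooth = 1L) {
  keep <- freqs >= band[1L] & freqs <= band[2L]
  f <- freqs[keep]; v <- values[keep]
  n <- length(v)
  if (n < 3L) return(list(freq = numeric(), height = numeric()))
  d <- diff(v)
  if (smooth > 1L) {
    kern <- rep(1 / smooth, smooth)
    d <- as.numeric(stats::filter(d, kern, sides = 2))
  }
  dl <- d[-(n - 1L)]; dr <- d[-1L]            # slopes around interior points
  i <- which(!is.na(dl) & !is.na(dr) & dl > 0 & dr <= 0) + 1L
  if (!length(i)) return(list(freq = numeric(), height = numeric()))
  y0 <- v[i]; ym <- v[i - 1L]; yp <- v[i + 1L]
  den <- ym - 2 * y0 + yp
  delta <- ifelse(den < 0, 0.5 * (ym - yp) / den, 0)
  delta <- pmax(pmin(delta, 0.5), -0.5)
  step <- f[2L] - f[1L]
  list(freq = f[i] + delta * step,
       height = y0 - 0.25 * (ym - yp) * delta)
}

#' Fit and derive bivariate spectra for one directed site pair
#'
#' Convenience wrapper: fits the bivariate model on \code{c(lower, higher)}
#' and returns its spectra. Column \code{"2->1"} of \code{$sgc} is the
#' top-down direction (higher -> lower), \code{"1->2"} bottom-up.
#'
#' @param ensemble mean-subtracted \code{\link{trial_ensemble}}.
#' @param pair length-2 integer vector \code{c(lower, higher)} of channel
#'   indices.
#' @param order model order (default 10).
#' @param freqs frequency grid.
#' @return list with \code{model} and \code{spectra}.
#' @export
pair_spectra <- function(ensemble, pair, order = 10L,
                         freqs = default_freqs()) {
  model <- fit_var(ensemble, channels = pair, order = order)
  list(model = model, spectra = model_spectra(model, freqs))
}
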