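#' Specification of a ground-truth oscillator network
#'
#' Describes a vector-autoregressive network of damped stochastic
#' oscillators split into a "lower" population (V1/V2-like) and a "higher"
#' population (V4/TEO-like). Each channel is an AR(2) resonator with pole
#' radius \code{osc_damping} at frequency \code{osc_freq}; directed coupling
#' is expressed as lagged cross-channel coefficients. Channels are ordered
#' lower first (\code{L1..}), then higher (\code{H1..}).
#'
#' @param n_lower number of lower-area channels.
#' @param n_higher number of higher-area channels.
#' @param osc_freq target resonance frequency in Hz (must be below Nyquist).
#' @param osc_damping pole radius r in (0, 1); closer to 1 gives a sharper
#'   spectral peak.
#' @param sampling_rate sampling rate in Hz used to convert \code{osc_freq}
#'   into AR(2) coefficients.
#' @param coupling data frame with columns \code{from}, \code{to} (channel
#'   labels such as \code{"H1"}, \code{"L2"}), \code{lag} (samples, >= 1)
#'   and \code{coef}. A row with \code{from} a higher channel and \code{to}
#'   a lower channel is a top-down edge; the reverse is bottom-up.
#' @param noise_cov innovation covariance matrix (channels x channels);
#'   defaults to the identity. Must be symmetric positive definite.
#' @param pink_noise_gain amplitude of 1/f-like background noise added to
#'   each channel after the VAR simulation (0 disables it). Either a single
#'   number or one value per channel.
#' @param mixing optional instantaneous channel-mixing matrix applied last
#'   (rows = output channels); used to build common-input confound fixtures.
#' @return an object of class \code{network_spec}.
#' @export
network_spec <- function(n_lower, n_higher, osc_freq = 16, osc_damping = 0.9,
                         sampling_rate = 200, coupling = NULL,
                         noise_cov = NULL, pink_noise_gain = 0,
                         mixing = NULL) {
  k <- n_lower + n_higher
  if (k < 1L) stop("need at least one channel")
  if (osc_freq >= sampling_rate / 2)
    stop("osc_freq must be below the Nyquist frequency")
  if (osc_damping < 0 || osc_damping >= 1)
    stop("osc_damping must lie in [0, 1)")
  labels <- c(if (n_lower) paste0("L", seq_len(n_lower)),
              if (n_higher) paste0("H", seq_len(n_higher)))
  if (is.null(coupling))
    coupling <- data.frame(from = character(), to = character(),
                           lag = integer(), coef = numeric())
  stopifnot(all(c("from", "to", "lag", "coef") %in% names(coupling)))
  if (nrow(coupling)) {
    if (!all(coupling$from %in% labels) || !all(coupling$to %in% labels))
      stop("coupling refers to unknown channel labels")
    if (any(coupling$lag < 1))
      stop("coupling lags must be >= 1 sample")
  }
  if (is.null(noise_cov)) noise_cov <- diag(k)
  noise_cov <- unname(as.matrix(noise_cov))
  if (!isTRUE(all.equal(noise_cov, t(noise_cov))) ||
      any(eigen(noise_cov, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("noise_cov must be symmetric positive definite")
  if (length(pink_noise_gain) == 1L)
    pink_noise_gain <- rep(pink_noise_gain, k)
  if (!is.null(mixing)) {
    mixing <- as.matrix(mixing)
    if (any(dim(mixing) != k)) stop("mixing must be channels x channels")
  }
  area <- c(rep("lower", n_lower), rep("higher", n_higher))
  structure(
    list(n_lower = n_lower, n_higher = n_higher, osc_freq = osc_freq,
         osc_damping = osc_damping, sampling_rate = sampling_rate,
         coupling = coupling, noise_cov = noise_cov,
         pink_noise_gain = pink_noise_gain, mixing = mixing,
         channel_labels = labels, area = stats::setNames(area, labels)),
    class = "network_spec")
}

#' Realize a network specification as explicit VAR coefficients
#'
#' Converts a \code{\link{network_spec}} into the coefficient array of the
#' implied VAR(p) process: every channel gets the AR(2) resonator
#' coefficients a1 = 2 r cos(2 pi f0 / rate), a2 = -r^2, and each coupling
#' row adds a lagged cross-channel coefficient. The result is checked for
#' stationarity via the spectral radius of the companion matrix.
#'
#' @param spec a \code{\link{network_spec}}.
#' @return list with \code{A} (array channels x channels x order;
#'   \code{A[i, j, l]} is the effect of channel j at lag l on channel i),
#'   \code{Sigma} (innovation covariance) and \code{spec}.
#' @export
build_var <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  k <- spec$n_lower + spec$n_higher
  p <- max(2L, if (nrow(spec$coupling)) max(spec$coupling$lag) else 0L)
  A <- array(0, dim = c(k, k, p))
  r <- spec$osc_damping
  a1 <- 2 * r * cos(2 * pi * spec$osc_freq / spec$sampling_rate)
  a2 <- -r^2
  for (i in seq_len(k)) {
    A[i, i, 1L] <- a1
    A[i, i, 2L] <- a2
  }
  if (nrow(spec$coupling)) {
    fi <- match(spec$coupling$from, spec$channel_labels)
    ti <- match(spec$coupling$to, spec$channel_labels)
    for (row in seq_len(nrow(spec$coupling)))
      A[ti[row], fi[row], spec$coupling$lag[row]] <-
        A[ti[row], fi[row], spec$coupling$lag[row]] + spec$coupling$coef[row]
  }
  rho <- companion_spectral_radius(A)
  if (rho >= 1)
    stop(sprintf(
      "specified network is non-stationary: companion spectral radius %.4f >= 1",
      rho))
  list(A = A, Sigma = spec$noise_cov, spec = spec)
}

#' Spectral radius of the VAR companion matrix
#'
#' @param A coefficient array channels x channels x order.
#' @return the largest eigenvalue modulus of the companion matrix; the
#'   process is (second-order) stationary iff this is < 1.
#' @export
companion_spectral_radius <- function(A) {
  k <- dim(A)[1L]; p <- dim(A)[3L]
  C <- matrix(0, k * p, k * p)
  for (l in seq_len(p))
    C[seq_len(k), (l - 1L) * k + seq_len(k)] <- A[, , l]
  if (p > 1L)
    C[k + seq_len(k * (p - 1L)), seq_len(k * (p - 1L))] <-
      diag(k * (p - 1L))
  max(Mod(eigen(C, only.values = TRUE)$values))
}

#' Paired-condition simulation specification
#'
#' Bundles a base network with per-condition modifications of its top-down
#' coupling, the trial geometry and the seed. Only top-down edges may
#' differ between the two behavioural contexts, so any decodable difference
#' is carried exclusively by the spatial pattern of top-down coupling.
#'
#' @param base a \code{\link{network_spec}}.
#' @param condition_deltas named list with elements \code{contingency1} and
#'   \code{contingency2}; each is a data frame with columns \code{from},
#'   \code{to}, \code{lag}, \code{factor} multiplying the matching coupling
#'   coefficient of \code{base}. All referenced edges must be top-down
#'   (higher -> lower).
#' @param trials_per_condition trial count per condition.
#' @param samples_per_trial samples per trial; default 17 (the floor of an
#'   85 ms epoch at 200 samples/s).
#' @param sampling_rate Hz; default 200.
#' @param burn_in samples discarded at the start of every trial so each
#'   trial is an independent draw from the stationary process; default 200.
#' @param seed integer seed driving the whole simulation.
#' @return an object of class \code{condition_pair_spec}.
#' @export
condition_pair_spec <- function(base, condition_deltas = NULL,
                                trials_per_condition = 1000L,
                                samples_per_trial = 17L,
                                sampling_rate = base$sampling_rate,
                                burn_in = 200L, seed = 1L) {
  stopifnot(inherits(base, "network_spec"))
  if (is.null(condition_deltas))
    condition_deltas <- list(
      contingency1 = data.frame(from = character(), to = character(),
                                lag = integer(), factor = numeric()),
      contingency2 = data.frame(from = character(), to = character(),
                                lag = integer(), factor = numeric()))
  stopifnot(all(c("contingency1", "contingency2") %in%
                  names(condition_deltas)))
  for (nm in c("contingency1", "contingency2")) {
    d <- condition_deltas[[nm]]
    if (nrow(d)) {
      ok <- base$area[d$from] == "higher" & base$area[d$to] == "lower"
      if (any(!ok | is.na(ok)))
        stop("condition deltas may only modify top-down (higher->lower) edges")
    }
  }
  structure(
    list(base = base, condition_deltas = condition_deltas,
         trials_per_condition = as.integer(trials_per_condition),
         samples_per_trial = as.integer(samples_per_trial),
         sampling_rate = sampling_rate, burn_in = as.integer(burn_in),
         seed = as.integer(seed)),
    class = "condition_pair_spec")
}

apply_deltas <- function(spec, deltas) {
  if (!nrow(deltas)) return(spec)
  cp <- spec$coupling
  for (row in seq_len(nrow(deltas))) {
    hit <- cp$from == deltas$from[row] & cp$to == deltas$to[row] &
      cp$lag == deltas$lag[row]
    if (!any(hit))
      stop("condition delta references a coupling edge absent from the base spec")
    cp$coef[hit] <- cp$coef[hit] * deltas$factor[row]
  }
  spec$coupling <- cp
  spec
}

# Fixed-coefficient pinking filter (cascade of three first-order sections,
# the classic -3 dB/octave approximation); applied columnwise to white
# noise. Coefficients are part of the stated generator, not tunable.
pink_filter <- function(x) {
  b <- c(0.049922035, -0.095993537, 0.050612699, -0.004408786)
  a <- c(2.494956002, -2.017265875, 0.522189400)  # recursive part (minus sign folded)
  fir <- stats::filter(x, b, method = "convolution", sides = 1)
  fir[is.na(fir)] <- 0
  y <- stats::filter(fir, a, method = "recursive")
  matrix(as.numeric(y), nrow = NROW(x))
}

#' Simulate a two-condition trial ensemble from a ground-truth network
#'
#' Draws independent trials from the stationary VAR processes implied by
#' the base network under each condition's top-down coupling modification.
#' Each trial gets its own burn-in, discarded before the epoch is kept, so
#' trials are independent realizations. Optional 1/f-like pink noise is
#' added per channel after the VAR recursion, and an optional instantaneous
#' mixing matrix is applied last. Identical seeds give bit-identical output.
#'
#' @param spec a \code{\link{condition_pair_spec}}.
#' @return a \code{\link{trial_ensemble}} with balanced condition labels
#'   (\code{"none"} when both condition deltas are empty and identical).
#' @export
simulate_trials <- function(spec) {
  stopifnot(inherits(spec, "condition_pair_spec"))
  base <- spec$base
  k <- base$n_lower + base$n_higher
  nper <- spec$trials_per_condition
  ns <- spec$samples_per_trial
  cond_names <- c("contingency1", "contingency2")
  labelled <- any(vapply(spec$condition_deltas, nrow, 0L) > 0L)
  with_seed(spec$seed, {
    blocks <- vector("list", 2L)
    for (ci in 1:2) {
      net <- build_var(apply_deltas(base, spec$condition_deltas[[cond_names[ci]]]))
      blocks[[ci]] <- simulate_var_block(net, nper, ns, spec$burn_in,
                                         base$pink_noise_gain, base$mixing)
    }
    data <- array(0, dim = c(2L * nper, k, ns))
    if (nper > 0L) {
      data[seq_len(nper), , ] <- blocks[[1L]]
      data[nper + seq_len(nper), , ] <- blocks[[2L]]
    }
    if (any(!is.finite(data)))
      stop("simulation produced non-finite values: stationarity violation")
    condition <- if (labelled)
      rep(cond_names, each = nper) else rep("none", 2L * nper)
    trial_ensemble(data, spec$sampling_rate, base$channel_labels,
                   base$area, condition)
  })
}

# Simulate `ntr` independent trials of `ns` samples from one realized
# network; all trials advance in lock-step through time so the recursion is
# a handful of matrix products per sample.
simulate_var_block <- function(net, ntr, ns, burn_in, pink_gain, mixing) {
  k <- dim(net$A)[1L]; p <- dim(net$A)[3L]
  total <- burn_in + ns
  if (ntr == 0L) return(array(0, dim = c(0L, k, ns)))
  L <- chol(net$Sigma)
  At <- lapply(seq_len(p), function(l) t(net$A[, , l]))
  X <- array(0, dim = c(ntr, k, total))
  innov <- array(stats::rnorm(ntr * total * k), dim = c(ntr, total, k))
  for (tt in seq_len(total)) {
    e <- innov[, tt, , drop = FALSE]
    dim(e) <- c(ntr, k)
    x <- e %*% L
    for (l in seq_len(min(p, tt - 1L)))
      x <- x + X[, , tt - l] %*% At[[l]]
    X[, , tt] <- x
  }
  out <- X[, , burn_in + seq_len(ns), drop = FALSE]
  if (any(pink_gain != 0)) {
    for (ch in seq_len(k)) {
      if (pink_gain[ch] == 0) next
      w <- matrix(stats::rnorm(total * ntr), nrow = total)
      pk <- pink_filter(w)[burn_in + seq_len(ns), , drop = FALSE]
      out[, ch, ] <- out[, ch, ] + pink_gain[ch] * t(pk)
    }
  }
  if (!is.null(mixing)) {
    Mt <- t(mixing)
    for (s in seq_len(ns)) out[, , s] <- out[, , s] %*% Mt
  }
  out
}

#' Canonical test network
#'
#' The fixed reference model used throughout the test suite and the
#' acceptance checks: 3 lower + 2 higher channels oscillating at 16 Hz with
#' pole radius 0.9 at 200 Hz, purely top-down coupling H1 -> L1 (0.25) and
#' H2 -> L2 (0.15) at lag 1, unit-diagonal innovations, and no pink noise
#' (so closed-form spectra from the true coefficients are exact oracles).
#'
#' @param pink_noise_gain optional 1/f background gain (default 0).
#' @return a \code{\link{network_spec}}.
#' @export
canonical_network <- function(pink_noise_gain = 0) {
  network_spec(
    n_lower = 3, n_higher = 2, osc_freq = 16, osc_damping = 0.9,
    sampling_rate = 200,
    coupling = data.frame(from = c("H1", "H2"), to = c("L1", "L2"),
                          lag = c(1L, 1L), coef = c(0.25, 0.15)),
    pink_noise_gain = pink_noise_gain)
}

#' Canonical two-condition simulation specification
#'
#' The canonical network with a +30\%/-30\% condition contrast on the
#' H1 -> L1 top-down edge: contingency 1 scales it by \code{1 + contrast},
#' contingency 2 by \code{1 - contrast}. With \code{contrast = 0} the two
#' conditions are statistically identical (the exchangeability null).
#'
#' @param trials_per_condition trials per condition.
#' @param contrast fractional coupling contrast (default 0.3).
#' @param seed integer seed.
#' @param samples_per_trial samples per trial (default 17).
#' @return a \code{\link{condition_pair_spec}}.
#' @export
canonical_conditions <- function(trials_per_condition = 2000L,
                                 contrast = 0.3, seed = 1L,
                                 samples_per_trial = 17L) {
  base <- canonical_network()
  condition_pair_spec(
    base,
    condition_deltas = list(
      contingency1 = data.frame(from = "H1", to = "L1", lag = 1L,
                                factor = 1 + contrast),
      contingency2 = data.frame(from = "H1", to = "L1", lag = 1L,
                                factor = 1 - contrast)),
    trials_per_condition = trials_per_condition,
    samples_per_trial = samples_per_trial, seed = seed)
}
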