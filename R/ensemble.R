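#' Trial-segmented multichannel ensemble
#'
#' Container for trial-segmented multichannel time series, the unit of
#' resampling for all spectral estimation. Data are stored as a numeric
#' array of dimension trials x channels x samples, in arbitrary amplitude
#' units, together with the sampling rate, a channel -> area map
#' (\code{"lower"} for V1/V2-like sites, \code{"higher"} for V4/TEO-like
#' sites) and a per-trial condition label.
#'
#' @param data numeric array, trials x channels x samples. All values must
#'   be finite.
#' @param sampling_rate sampling rate in Hz (single positive number).
#' @param channel_labels character vector of channel names, one per channel.
#' @param area character vector (\code{"lower"}/\code{"higher"}), one per
#'   channel, naming the cortical level each channel records from.
#' @param condition per-trial condition label; factor or character with
#'   levels among \code{"contingency1"}, \code{"contingency2"},
#'   \code{"none"}. Defaults to \code{"none"} for every trial.
#' @return an object of class \code{trial_ensemble}.
#' @export
trial_ensemble <- function(data, sampling_rate, channel_labels = NULL,
                           area, condition = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-d array (trials x channels x samples)")
  if (any(!is.finite(data)))
    stop("`data` contains non-finite values")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0)
    stop("`sampling_rate` must be a single positive number")
  k <- dim(data)[2L]
  n <- dim(data)[1L]
  if (is.null(channel_labels))
    channel_labels <- paste0("ch", seq_len(k))
  if (length(channel_labels) != k)
    stop("`channel_labels` must have one entry per channel")
  if (length(area) != k || !all(area %in% c("lower", "higher")))
    stop("every channel must be assigned an area ('lower' or 'higher')")
  if (is.null(condition))
    condition <- rep("none", n)
  condition <- as.character(condition)
  if (length(condition) != n)
    stop("`condition` must have one entry per trial")
  bad <- setdiff(unique(condition), c("contingency1", "contingency2", "none"))
  if (length(bad))
    stop("unknown condition label(s): ", paste(bad, collapse = ", "))
  area <- stats::setNames(as.character(area), channel_labels)
  structure(
    list(data = data, sampling_rate = sampling_rate,
         channel_labels = channel_labels, area = area,
         condition = condition),
    class = "trial_ensemble")
}

#' @export
print.trial_ensemble <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<trial_ensemble> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1L], d[2L], d[3L], x$sampling_rate))
  cat("  channels:", paste(sprintf("%s(%s)", x$channel_labels,
                                   substr(x$area, 1, 1)), collapse = " "),
      "\n")
  tab <- table(x$condition)
  cat("  conditions:", paste(sprintf("%s=%d", names(tab), tab),
                             collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.trial_ensemble <- function(x) dim(x$data)

#' Number of trials in an ensemble
#' @param ensemble a \code{\link{trial_ensemble}}.
#' @return integer trial count.
#' @export
n_trials <- function(ensemble) dim(ensemble$data)[1L]

#' Subset an ensemble by trial index
#'
#' @param ensemble a \code{\link{trial_ensemble}}.
#' @param trials integer vector of trial indices (duplicates allowed, so
#'   this also materializes bootstrap resamples).
#' @return a \code{trial_ensemble} holding the selected trials.
#' @export
subset_trials <- function(ensemble, trials) {
  trial_ensemble(ensemble$data[trials, , , drop = FALSE],
                 ensemble$sampling_rate, ensemble$channel_labels,
                 ensemble$area, ensemble$condition[trials])
}

#' Reverse time within each trial
#'
#' Flips the sample axis of every trial, leaving trial order, channel
#' metadata and condition labels untouched. Used by the time-reversal
#' control: genuinely lagged causality changes direction under reversal,
#' while instantaneous (common-input) structure does not.
#'
#' @param ensemble a \code{\link{trial_ensemble}}.
#' @return the time-reversed \code{trial_ensemble}.
#' @export
reverse_time <- function(ensemble) {
  ns <- dim(ensemble$data)[3L]
  trial_ensemble(ensemble$data[, , ns:1, drop = FALSE],
                 ensemble$sampling_rate, ensemble$channel_labels,
                 ensemble$area, ensemble$condition)
}

#' Subtract the across-trial ensemble mean
#'
#' Removes, per channel and sample index, the mean over trials from every
#' trial, so that each trial approximates a realization of a zero-mean
#' stochastic process as required by the AR modelling step.
#'
#' @param ensemble a \code{\link{trial_ensemble}} with at least 2 trials.
#' @return a \code{trial_ensemble} whose across-trial mean is exactly zero
#'   at every (channel, sample).
#' @export
subtract_ensemble_mean <- function(ensemble) {
  n <- n_trials(ensemble)
  if (n < 2L)
    stop("ensemble-mean subtraction needs >= 2 trials ",
         "(with a single trial it would zero the data)")
  m <- colMeans(ensemble$data)              # channels x samples
  d <- ensemble$data - rep(m, each = n)     # broadcast over trials
  trial_ensemble(d, ensemble$sampling_rate, ensemble$channel_labels,
                 ensemble$area, ensemble$condition)
}

#' All lower-higher channel pairs of an ensemble
#'
#' @param ensemble a \code{\link{trial_ensemble}}.
#' @return two-column integer matrix with columns \code{lower} and
#'   \code{higher}; one row per (lower-area, higher-area) channel pair.
#' @export
area_pairs <- function(ensemble) {
  lo <- which(ensemble$area == "lower")
  hi <- which(ensemble$area == "higher")
  if (!length(lo) || !length(hi))
    stop("ensemble must contain at least one channel per area")
  out <- as.matrix(expand.grid(lower = lo, higher = hi,
                               KEEP.OUT.ATTRS = FALSE))
  storage.mode(out) <- "integer"
  out
}

pair_label <- function(ensemble, pair) {
  paste0(ensemble$channel_labels[pair[2L]], "->",
         ensemble$channel_labels[pair[1L]])
}

# Evaluate `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. All randomized routines in the package go
# through this; there is no hidden global random state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}
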