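# Container I/O, configuration and the end-to-end driver.
#
# Ensembles live in a directory holding `data.csv` (one row per
# trial x channel, sample columns s1..sT) and `meta.json` (schema_version,
# sampling_rate, channel_labels, areas, conditions). Everything round-trips
# losslessly; all schemas carry a schema_version field.

ENSEMBLE_SCHEMA_VERSION <- "1"

#' Write a trial ensemble to a directory
#'
#' @param ensemble a \code{\link{trial_ensemble}}.
#' @param path directory (created if absent); receives \code{data.csv} and
#'   \code{meta.json}.
#' @return \code{path}, invisibly.
#' @export
write_ensemble <- function(ensemble, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(ensemble$data)
  flat <- matrix(aperm(ensemble$data, c(3L, 2L, 1L)), ncol = d[3L],
                 byrow = TRUE)
  df <- data.frame(trial = rep(seq_len(d[1L]), each = d[2L]),
                   channel = rep(ensemble$channel_labels, d[1L]))
  df <- cbind(df, as.data.frame(flat))
  names(df)[-(1:2)] <- paste0("s", seq_len(d[3L]))
  utils::write.csv(df, file.path(path, "data.csv"), row.names = FALSE)
  meta <- list(schema_version = ENSEMBLE_SCHEMA_VERSION,
               sampling_rate = ensemble$sampling_rate,
               channel_labels = ensemble$channel_labels,
               areas = unname(ensemble$area),
               conditions = ensemble$condition)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a trial ensemble from a directory
#'
#' @param path directory written by \code{\link{write_ensemble}}.
#' @return a \code{\link{trial_ensemble}} (bit-for-bit round-trip of data
#'   and metadata).
#' @export
read_ensemble <- function(path) {
  meta_file <- file.path(path, "meta.json")
  data_file <- file.path(path, "data.csv")
  if (!file.exists(meta_file)) stop("missing meta.json in ", path)
  if (!file.exists(data_file)) stop("missing data.csv in ", path)
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  required <- c("schema_version", "sampling_rate", "channel_labels",
                "areas", "conditions")
  absent <- setdiff(required, names(meta))
  if (length(absent))
    stop("ensemble metadata schema error: missing key(s) ",
         paste(absent, collapse = ", "))
  if (meta$sampling_rate <= 0) stop("sampling_rate must be positive")
  df <- utils::read.csv(data_file, check.names = FALSE)
  k <- length(meta$channel_labels)
  ntr <- nrow(df) / k
  scols <- grep("^s[0-9]+$", names(df))
  flat <- as.matrix(df[, scols, drop = FALSE])
  data <- aperm(array(t(flat), dim = c(length(scols), k, ntr)),
                c(3L, 2L, 1L))
  trial_ensemble(data, meta$sampling_rate, meta$channel_labels,
                 meta$areas, meta$conditions)
}

#' Analysis run configuration
#'
#' Bundles every tunable of the pipeline; defaults equal the reference
#' protocol values wherever one exists (model order 10, band 5-90 Hz, 1/f
#' fit band 5-30 Hz, 1000 bootstraps, 1000 null permutations, asymmetry
#' alpha 0.001, peak level 0.05, 200 exemplars, 5000 repeats, cost 1,
#' control frequencies 5-50 Hz). Round-trips losslessly through JSON via
#' \code{\link{write_config}} / \code{\link{read_config}}.
#'
#' @param simulation optional \code{\link{condition_pair_spec}} (built when
#'   \code{input} is NULL via \code{\link{canonical_conditions}} arguments
#'   supplied here).
#' @param input optional path of an ensemble directory to analyse.
#' @param order model order.
#' @param order_scan AIC scan range.
#' @param band analysis band (Hz).
#' @param freq_step frequency grid step (Hz).
#' @param fit_band 1/f robust-fit band (Hz).
#' @param B bootstrap count.
#' @param n_null permutation count for the peak null.
#' @param alpha_asymmetry two-tailed level of the asymmetry test.
#' @param alpha_peak peak significance level.
#' @param B_exemplars decoder exemplars per block.
#' @param repeats decoder jackknife repeats.
#' @param cost SVM cost parameter.
#' @param target_freq decoder target frequency (Hz).
#' @param control_range control decoder frequency range (Hz).
#' @param seed master seed; stage seeds are derived deterministically.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(simulation = NULL, input = NULL, order = 10L,
                       order_scan = 5:15, band = c(5, 90), freq_step = 1,
                       fit_band = c(5, 30), B = 1000L, n_null = 1000L,
                       alpha_asymmetry = 0.001, alpha_peak = 0.05,
                       B_exemplars = 200L, repeats = 5000L, cost = 1,
                       target_freq = 16, control_range = c(5, 50),
                       seed = 1L) {
  structure(list(simulation = simulation, input = input,
                 order = as.integer(order),
                 order_scan = as.integer(order_scan), band = band,
                 freq_step = freq_step, fit_band = fit_band,
                 B = as.integer(B), n_null = as.integer(n_null),
                 alpha_asymmetry = alpha_asymmetry,
                 alpha_peak = alpha_peak,
                 B_exemplars = as.integer(B_exemplars),
                 repeats = as.integer(repeats), cost = cost,
                 target_freq = target_freq, control_range = control_range,
                 seed = as.integer(seed),
                 schema_version = ENSEMBLE_SCHEMA_VERSION),
            class = "run_config")
}

#' @rdname run_config
#' @param config a \code{run_config}.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$simulation <- if (!is.null(x$simulation)) serialize_sim(x$simulation)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim <- if (!is.null(x$simulation)) deserialize_sim(x$simulation)
  do.call(run_config, c(list(simulation = sim),
                        x[setdiff(names(x),
                                  c("simulation", "schema_version"))]))
}

serialize_sim <- function(sim) {
  b <- sim$base
  list(n_lower = b$n_lower, n_higher = b$n_higher, osc_freq = b$osc_freq,
       osc_damping = b$osc_damping, sampling_rate = b$sampling_rate,
       coupling = b$coupling, noise_cov = b$noise_cov,
       pink_noise_gain = b$pink_noise_gain,
       mixing = b$mixing,
       condition_deltas = sim$condition_deltas,
       trials_per_condition = sim$trials_per_condition,
       samples_per_trial = sim$samples_per_trial, burn_in = sim$burn_in,
       seed = sim$seed)
}

deserialize_sim <- function(x) {
  df_or_null <- function(d) {
    d <- as.data.frame(d)
    if (!nrow(d) || !ncol(d)) NULL else d
  }
  base <- network_spec(
    n_lower = x$n_lower, n_higher = x$n_higher, osc_freq = x$osc_freq,
    osc_damping = x$osc_damping, sampling_rate = x$sampling_rate,
    coupling = df_or_null(x$coupling),
    noise_cov = as.matrix(x$noise_cov),
    pink_noise_gain = x$pink_noise_gain,
    mixing = if (!is.null(x$mixing)) as.matrix(x$mixing))
  empty_delta <- data.frame(from = character(), to = character(),
                            lag = integer(), factor = numeric())
  condition_pair_spec(
    base,
    condition_deltas = lapply(x$condition_deltas, function(d) {
      d <- df_or_null(d)
      if (is.null(d)) empty_delta else d
    }),
    trials_per_condition = x$trials_per_condition,
    samples_per_trial = x$samples_per_trial,
    sampling_rate = x$sampling_rate, burn_in = x$burn_in, seed = x$seed)
}

stage_seed <- function(seed, stage) {
  (as.integer(seed) * 131L + stage * 7919L) %% 2147483629L
}

#' Run the full analysis pipeline
#'
#' Sequences the complete analysis: simulate (or load) -> ensemble-mean
#' subtraction -> AIC order check -> bootstrap spectra -> 1/f-removed power
#' -> directional asymmetry -> peak detection with permutation null ->
#' consistent-pair selection -> time-reversal control -> coherence/sGC
#' correlation -> context decoding with random-frequency control. Writes
#' tidy CSV tables, a JSON summary and a provenance log under
#' \code{outdir}; the same config and seed reproduce the summary exactly.
#'
#' @param config a \code{\link{run_config}}.
#' @param outdir output directory.
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s (partial outputs in %s)",
                   name, conditionMessage(e), outdir), call. = FALSE))
  }
  ensemble <- stage("input", {
    if (!is.null(config$input)) read_ensemble(config$input)
    else if (!is.null(config$simulation)) simulate_trials(config$simulation)
    else stop("config provides neither an input path nor a simulation spec")
  })
  freqs <- seq(config$band[1L], config$band[2L], by = config$freq_step)
  ens0 <- stage("mean_subtraction", subtract_ensemble_mean(ensemble))
  pairs <- area_pairs(ens0)
  aic <- stage("aic", select_order_aic(ens0, pairs[1L, ],
                                       orders = config$order_scan))
  boot <- stage("bootstrap_spectra",
                bootstrap_spectra(ens0, pairs, order = config$order,
                                  freqs = freqs, B = config$B,
                                  seed = stage_seed(config$seed, 1L)))
  power_mean <- rowMeans(vapply(boot$full, function(s) s$power[, 1L],
                                numeric(length(freqs))))
  bg <- stage("background_removal",
              remove_background(power_mean, freqs,
                                fit_band = config$fit_band))
  asym <- stage("asymmetry", directional_asymmetry(
    apply(boot$td, c(1L, 2L), mean), apply(boot$bu, c(1L, 2L), mean),
    n = n_trials(ens0), alpha = config$alpha_asymmetry, freqs = freqs))
  null <- stage("peak_null", peak_null_threshold(
    ens0, pairs, order = config$order, freqs = freqs,
    n_null = config$n_null, seed = stage_seed(config$seed, 2L),
    q = 1 - config$alpha_peak))
  peaks <- stage("peaks", peak_table(boot, null$threshold,
                                     band = config$band))
  target <- stage("modal_frequency", {
    if (any(peaks$significant %in% TRUE))
      modal_peak_frequency(peaks, band = config$band)$mode
    else config$target_freq
  })
  sel <- stage("pair_selection",
               select_consistent_pairs(peaks, target, n = n_trials(ens0)))
  band_sig <- if (any(asym$significant))
    range(freqs[asym$significant]) else config$band
  trt <- stage("time_reversal",
               time_reversal_test(ens0, pairs, band_sig,
                                  order = config$order, freqs = freqs))
  fi <- which.min(abs(freqs - target))
  corr <- stage("coherence_correlation", {
    if (nrow(pairs) >= 3L)
      coherence_gc_correlation(boot$td[, fi, ], boot$coherence[, fi, ])
    else NULL
  })
  dec <- dec_ctrl <- NULL
  if (all(c("contingency1", "contingency2") %in% ens0$condition)) {
    dpairs <- pairs[intersect(sel$retained, seq_len(nrow(pairs))), ,
                    drop = FALSE]
    if (!nrow(dpairs)) dpairs <- pairs
    dec <- stage("decode", decode_context(
      ens0, dpairs, order = config$order, freqs = freqs,
      band = config$band, B_exemplars = config$B_exemplars,
      repeats = config$repeats, cost = config$cost,
      target_freq = config$target_freq,
      seed = stage_seed(config$seed, 3L)))
    dec_ctrl <- stage("decode_control", control_decode(
      ens0, dpairs, order = config$order, freqs = freqs,
      band = config$band, B_exemplars = config$B_exemplars,
      repeats = config$repeats, cost = config$cost,
      freq_range = config$control_range,
      seed = stage_seed(config$seed, 4L)))
  }
  # ---- outputs -----------------------------------------------------------
  utils::write.csv(spectra_tidy(boot), file.path(outdir, "spectra.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(peaks), file.path(outdir, "peaks.csv"),
                   row.names = FALSE)
  utils::write.csv(trt, file.path(outdir, "time_reversal.csv"),
                   row.names = FALSE)
  summary <- list(
    schema_version = ENSEMBLE_SCHEMA_VERSION,
    n_trials = n_trials(ens0),
    aic_order = aic$order,
    asymmetry = list(significant_freqs = freqs[asym$significant],
                     se_omnibus = asym$se_omnibus),
    background = list(coef = as.list(bg$coef)),
    peak_null_threshold = null$threshold,
    modal_peak_freq = target,
    retained_pairs = sel$retained_labels,
    pair_selection_ci = sel$ci,
    time_reversal_genuine = stats::setNames(trt$genuine, trt$pair),
    coherence_r_squared = if (!is.null(corr)) corr$r_squared,
    decoding = if (!is.null(dec)) list(
      accuracy = dec$mean_accuracy, se_jsve = dec$se_jsve,
      t = dec$t_stat, p = dec$p_value),
    decoding_control = if (!is.null(dec_ctrl)) list(
      accuracy = dec_ctrl$mean_accuracy, p = dec_ctrl$p_value))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  prov <- list(package = "betaflow",
               version = as.character(utils::packageVersion("betaflow")),
               r_version = R.version.string,
               seed = config$seed,
               stage_seeds = vapply(1:4, stage_seed,
                                    seed = config$seed, numeric(1)),
               B = config$B, n_null = config$n_null,
               repeats = config$repeats,
               elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                               units = "secs")))
  jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(summary)
}

# Tidy per-bootstrap spectra: one row per (bootstrap, kind, pair, freq).
spectra_tidy <- function(boot) {
  np <- dim(boot$td)[3L]
  rows <- list()
  for (pi in seq_len(np)) {
    lab <- strsplit(boot$pair_labels[pi], "->", fixed = TRUE)[[1L]]
    full <- boot$full[[pi]]
    rows[[pi]] <- data.frame(
      bootstrap_id = 0L,
      kind = rep(c("power", "power", "coherence", "sgc", "sgc"),
                 each = length(boot$freqs)),
      source = rep(c(lab[2L], lab[1L], lab[2L], lab[1L], lab[2L]),
                   each = length(boot$freqs)),
      target = rep(c(lab[2L], lab[1L], lab[1L], lab[2L], lab[1L]),
                   each = length(boot$freqs)),
      freq_hz = rep(boot$freqs, 5L),
      value = c(full$power[, 2L], full$power[, 1L], full$coherence[, 1L],
                full$sgc[, 2L], full$sgc[, 1L]))
  }
  do.call(rbind, rows)
}

#' Command-line entry point
#'
#' Subcommand dispatcher used by \code{inst/cli/betaflow.R}:
#' \code{simulate}, \code{report} (full pipeline) and \code{config}
#' (write a default config). Each subcommand consumes/produces files so
#' stages can be re-run independently.
#'
#' @param args character vector of CLI arguments (default
#'   \code{commandArgs(trailingOnly = TRUE)}).
#' @return exit status, invisibly.
#' @export
betaflow_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: betaflow <command> [options]",
    "  config   --out <config.json>            write the default config",
    "  simulate --config <config.json> --out <dir>   simulate an ensemble",
    "  report   --config <config.json> --out <dir>   run the full pipeline",
    sep = "\n")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1L]
  opt <- function(flag) {
    i <- which(args == flag)
    if (!length(i) || i == length(args)) stop("missing value for ", flag)
    args[i + 1L]
  }
  switch(cmd,
    config = {
      cfg <- run_config(simulation = canonical_conditions())
      write_config(cfg, opt("--out"))
    },
    simulate = {
      cfg <- read_config(opt("--config"))
      if (is.null(cfg$simulation)) stop("config has no simulation spec")
      write_ensemble(simulate_trials(cfg$simulation), opt("--out"))
    },
    report = {
      cfg <- read_config(opt("--config"))
      run_pipeline(cfg, opt("--out"))
    },
    stop("unknown command '", cmd, "'\n", usage))
  invisible(0L)
}
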