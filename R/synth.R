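#' Gaussian beat template
#'
#' A heartbeat is modelled as a sum of Gaussian deflections, one per ECG wave
#' (P, Q, R, S, T).  Each wave has an amplitude in mV, a centre offset in
#' seconds relative to the R peak, and a Gaussian width (standard deviation)
#' in seconds.  The analytic form gives exact control of the R- and T-wave
#' amplitudes, so the T:R ratio of a generated beat is known by construction:
#' it is `abs(T amplitude) / abs(R amplitude)`.
#'
#' @param p,q,r,s,t numeric length-3 vectors `c(amplitude_mv, center_s,
#'   width_s)` for the five waves.  R amplitude must be positive and T
#'   amplitude non-negative.
#' @return An object of class `beat_template`.
#' @examples
#' tpl <- beat_template()
#' tr_of_template(tpl)  # 0.25 with the defaults
#' @export
beat_template <- function(p = c(0.10, -0.20, 0.025),
                          q = c(-0.08, -0.030, 0.010),
                          r = c(1.00, 0.000, 0.012),
                          s = c(-0.12, 0.030, 0.010),
                          t = c(0.25, 0.300, 0.060)) {
  waves <- rbind(P = p, Q = q, R = r, S = s, T = t)
  colnames(waves) <- c("amp_mv", "center_s", "width_s")
  stop_if_not(all(is.finite(waves)), "beat template parameters must be finite")
  stop_if_not(all(waves[, "width_s"] > 0), "wave widths must be positive")
  stop_if_not(waves["R", "amp_mv"] > 0, "R amplitude must be positive")
  stop_if_not(waves["T", "amp_mv"] >= 0, "T amplitude must be non-negative")
  structure(list(waves = waves), class = "beat_template")
}

#' @rdname beat_template
#' @param template a `beat_template`
#' @export
tr_of_template <- function(template) {
  w <- template$waves
  abs(w["T", "amp_mv"]) / abs(w["R", "amp_mv"])
}

#' Evaluate a beat template at time offsets
#'
#' @param template a [beat_template()]
#' @param t_s numeric vector of offsets in seconds relative to the R peak
#' @param waves which waves to include (default all five)
#' @return numeric vector of amplitudes in mV
#' @export
eval_template <- function(template, t_s, waves = rownames(template$waves)) {
  w <- template$waves[waves, , drop = FALSE]
  out <- numeric(length(t_s))
  for (i in seq_len(nrow(w))) {
    out <- out + w[i, "amp_mv"] * exp(-((t_s - w[i, "center_s"])^2) /
                                        (2 * w[i, "width_s"]^2))
  }
  out
}

#' T:R trajectory helpers
#'
#' A trajectory is a function of time (seconds since recording start)
#' returning the target T:R ratio.  `tr_constant()` is flat, `tr_diurnal()`
#' adds a slow sinusoidal (circadian-like) modulation, and `tr_step()` is
#' piecewise constant over given breakpoints.
#'
#' @param value,mean,amplitude T:R levels (unitless, must be non-negative
#'   where evaluated)
#' @param period_s period of the diurnal modulation, default one day
#' @param phase_s time offset of the modulation peak
#' @param breaks_s,values breakpoints (seconds) and the value on each of the
#'   `length(breaks_s) + 1` intervals
#' @return a function `f(t_s) -> T:R`
#' @export
tr_constant <- function(value) {
  force(value)
  function(t_s) rep(value, length(t_s))
}

#' @rdname tr_constant
#' @export
tr_diurnal <- function(mean = 0.25, amplitude = 0.08, period_s = 86400,
                       phase_s = 0) {
  force(mean); force(amplitude); force(period_s); force(phase_s)
  function(t_s) mean + amplitude * sin(2 * pi * (t_s - phase_s) / period_s)
}

#' @rdname tr_constant
#' @export
tr_step <- function(breaks_s, values) {
  stop_if_not(length(values) == length(breaks_s) + 1,
              "need one value per interval (length(breaks_s) + 1)")
  force(breaks_s); force(values)
  function(t_s) values[findInterval(t_s, breaks_s) + 1]
}

#' Synthetic Holter configuration
#'
#' Parameters of the synthetic three-channel 24-h Holter generator.  The
#' three channels are surrogates of the S-ICD primary, alternate and
#' secondary sensing vectors; per-channel gains scale the whole waveform
#' (leaving T:R unchanged) while per-channel T-wave gains scale only the
#' T wave, so the vectors can disagree on eligibility.
#'
#' @param duration_s recording length in seconds (default 86400, i.e. 24 h)
#' @param sampling_rate_hz sampling rate (default 500 Hz)
#' @param heart_rate_bpm mean heart rate
#' @param rr_jitter_sd_s SD of i.i.d. Gaussian jitter on inter-beat
#'   intervals; intervals are clipped to >= 0.3 s so beats never overlap
#' @param tr_trajectory function giving the target T:R at time t (seconds);
#'   see [tr_constant()], [tr_diurnal()], [tr_step()]
#' @param tr_ar1_sd,tr_ar1_phi innovation SD and autocorrelation of an AR(1)
#'   jitter added to the trajectory per 10-s segment (set sd to 0 for an
#'   exactly programmed trajectory)
#' @param channel_gain length-3 gains for (primary, alternate, secondary)
#' @param t_gain length-3 T-wave-only gain multipliers per channel
#' @param baseline_wander_mv,baseline_wander_hz amplitude and frequency of
#'   sinusoidal baseline wander (respiration-like)
#' @param powerline_mv,powerline_hz amplitude and frequency of mains
#'   interference (default 50 Hz)
#' @param white_noise_sd_mv SD of additive broadband Gaussian noise
#' @param template a [beat_template()]; its T amplitude is overridden
#'   beat-by-beat to follow `tr_trajectory`
#' @param rng_seed integer seed; identical configurations and seeds give
#'   bit-identical recordings
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(duration_s = 86400,
                         sampling_rate_hz = 500,
                         heart_rate_bpm = 60,
                         rr_jitter_sd_s = 0.04,
                         tr_trajectory = tr_diurnal(),
                         tr_ar1_sd = 0.01,
                         tr_ar1_phi = 0.9,
                         channel_gain = c(primary = 1.0, alternate = 0.8,
                                          secondary = 0.9),
                         t_gain = c(primary = 1, alternate = 1, secondary = 1),
                         baseline_wander_mv = 0.15,
                         baseline_wander_hz = 0.25,
                         powerline_mv = 0.05,
                         powerline_hz = 50,
                         white_noise_sd_mv = 0.02,
                         template = beat_template(),
                         rng_seed = 1L) {
  cfg <- structure(
    list(duration_s = duration_s, sampling_rate_hz = sampling_rate_hz,
         heart_rate_bpm = heart_rate_bpm, rr_jitter_sd_s = rr_jitter_sd_s,
         tr_trajectory = tr_trajectory, tr_ar1_sd = tr_ar1_sd,
         tr_ar1_phi = tr_ar1_phi,
         channel_gain = unname(channel_gain), t_gain = unname(t_gain),
         baseline_wander_mv = baseline_wander_mv,
         baseline_wander_hz = baseline_wander_hz,
         powerline_mv = powerline_mv, powerline_hz = powerline_hz,
         white_noise_sd_mv = white_noise_sd_mv,
         template = template, rng_seed = as.integer(rng_seed)),
    class = "synth_config")
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  stop_if_not(is.numeric(cfg$duration_s) && cfg$duration_s > 0,
              "configuration error: duration_s must be positive")
  stop_if_not(is.numeric(cfg$sampling_rate_hz) && cfg$sampling_rate_hz > 0,
              "configuration error: sampling_rate_hz must be positive")
  stop_if_not(cfg$heart_rate_bpm > 0,
              "configuration error: heart_rate_bpm must be positive")
  stop_if_not(is.function(cfg$tr_trajectory),
              "configuration error: tr_trajectory must be a function")
  amps <- c(cfg$baseline_wander_mv, cfg$powerline_mv, cfg$white_noise_sd_mv,
            cfg$tr_ar1_sd)
  stop_if_not(all(amps >= 0),
              "configuration error: noise amplitudes must be non-negative")
  stop_if_not(length(cfg$channel_gain) == 3 && length(cfg$t_gain) == 3,
              "configuration error: channel_gain and t_gain need 3 values")
  invisible(cfg)
}

#' Generate a synthetic three-channel Holter recording
#'
#' Places beats by an inter-beat interval process (mean `60/heart_rate_bpm`
#' with clipped Gaussian jitter), renders each beat from the Gaussian
#' template with the T-wave amplitude scaled so that the beat's T:R equals
#' the programmed trajectory value of its 10-s segment, applies per-channel
#' gains, and adds baseline wander, mains interference and white noise.
#' The realised per-segment, per-channel T:R (trajectory plus AR(1) jitter,
#' times the channel's T-wave gain) is returned as ground truth.
#'
#' @param config a [synth_config()]
#' @return A list with elements `record` (an [ecg_record]) and
#'   `ground_truth`, itself a list of `tr` (tibble: `segment` 0-based,
#'   `channel`, `tr`), `beats` (tibble: `time_s`, `r_amp_mv`, `t_amp_mv`)
#'   and `segment_s` (the 10-s segmentation grid the truth refers to).
#' @examples
#' sim <- generate_recording(synth_config(duration_s = 60, rng_seed = 7))
#' sim$record
#' head(sim$ground_truth$tr)
#' @export
generate_recording <- function(config) {
  validate_synth_config(config)
  fs <- config$sampling_rate_hz
  n <- as.integer(round(config$duration_s * fs))
  seg_s <- 10
  n_seg <- max(1L, floor(config$duration_s / seg_s))

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$rng_seed)

  # beat times: clipped-Gaussian inter-beat intervals
  rr_mean <- 60 / config$heart_rate_bpm
  n_max <- ceiling(config$duration_s / max(0.3, rr_mean - 4 * config$rr_jitter_sd_s)) + 2L
  rr <- pmax(0.3, stats::rnorm(n_max, rr_mean, config$rr_jitter_sd_s))
  beat_t <- 0.4 + cumsum(c(0, rr))
  beat_t <- beat_t[beat_t < config$duration_s - 1e-9]
  n_beats <- length(beat_t)

  # per-segment programmed T:R = trajectory + AR(1) jitter, clipped at 0
  seg_start <- (seq_len(n_seg) - 1) * seg_s
  tr_base <- config$tr_trajectory(seg_start + seg_s / 2)
  if (any(tr_base < 0))
    stop("domain error: tr_trajectory returned negative values", call. = FALSE)
  if (config$tr_ar1_sd > 0) {
    e <- numeric(n_seg)
    innov <- stats::rnorm(n_seg, 0, config$tr_ar1_sd)
    e[1] <- innov[1]
    if (n_seg > 1) for (i in 2:n_seg) e[i] <- config$tr_ar1_phi * e[i - 1] + innov[i]
    tr_seg <- pmax(0, tr_base + e)
  } else {
    tr_seg <- tr_base
  }

  # render: channel-independent accumulation of the fixed (P,Q,R,S) part and
  # a unit-T part weighted by each beat's target T amplitude
  w <- config$template$waves
  r_amp <- w["R", "amp_mv"]
  offs <- seq.int(round(-0.35 * fs), round(0.60 * fs))
  fixed_shape <- eval_template(config$template, offs / fs, c("P", "Q", "R", "S"))
  t_shape <- exp(-((offs / fs - w["T", "center_s"])^2) / (2 * w["T", "width_s"]^2))

  beat_seg <- pmin(n_seg, floor(beat_t / seg_s) + 1L)
  beat_tr <- tr_seg[beat_seg]
  beat_tamp <- beat_tr * r_amp

  base_sig <- numeric(n)
  t_sig <- numeric(n)
  beat_idx0 <- as.integer(round(beat_t * fs)) + 1L
  for (b in seq_len(n_beats)) {
    idx <- beat_idx0[b] + offs
    keep <- idx >= 1L & idx <= n
    i <- idx[keep]
    base_sig[i] <- base_sig[i] + fixed_shape[keep]
    t_sig[i] <- t_sig[i] + beat_tamp[b] * t_shape[keep]
  }

  tt <- seq.int(0L, n - 1L) / fs
  labels <- vector_labels()
  samples <- matrix(0, nrow = n, ncol = 3, dimnames = list(NULL, labels))
  for (c in 1:3) {
    sig <- config$channel_gain[c] * (base_sig + config$t_gain[c] * t_sig)
    if (config$baseline_wander_mv > 0)
      sig <- sig + config$baseline_wander_mv *
        sin(2 * pi * config$baseline_wander_hz * tt + stats::runif(1, 0, 2 * pi))
    if (config$powerline_mv > 0)
      sig <- sig + config$powerline_mv *
        sin(2 * pi * config$powerline_hz * tt + stats::runif(1, 0, 2 * pi))
    if (config$white_noise_sd_mv > 0)
      sig <- sig + stats::rnorm(n, 0, config$white_noise_sd_mv)
    samples[, c] <- sig
  }

  record <- ecg_record(samples, sampling_rate_hz = fs, channel_labels = labels)
  gt_tr <- tibble::tibble(
    segment = rep(seq_len(n_seg) - 1L, times = 3),
    channel = rep(labels, each = n_seg),
    tr = as.vector(outer(tr_seg, config$t_gain)))
  ground_truth <- list(
    tr = gt_tr,
    beats = tibble::tibble(time_s = beat_t, r_amp_mv = r_amp,
                           t_amp_mv = beat_tamp),
    segment_s = seg_s)
  list(record = record, ground_truth = ground_truth)
}

#' Write a recording to plain-text ASCII
#'
#' The dialect is `#`-prefixed header lines (`# fs=500`,
#' `# channels=primary,alternate,secondary`) followed by one row per sample
#' with one tab- or comma-separated column per channel, amplitudes in mV.
#' `read_ascii(write_ascii(x))` reproduces the samples up to the printed
#' precision.
#'
#' @param record an [ecg_record]
#' @param path output file path
#' @param sep column separator, tab or comma
#' @param digits decimal digits printed
#' @param header write the metadata header lines?
#' @return `path`, invisibly.
#' @export
write_ascii <- function(record, path, sep = "\t", digits = 6, header = TRUE) {
  stop_if_not(inherits(record, "ecg_record"), "record must be an ecg_record")
  stop_if_not(ncol(record$samples) >= 1 && nrow(record$samples) >= 1,
              "empty record: nothing to write")
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("I/O error: cannot open '", path,
                                           "' for writing", call. = FALSE))
  on.exit(close(con))
  if (header) {
    writeLines(c(sprintf("# fs=%g", record$sampling_rate_hz),
                 paste0("# channels=", paste(record$channel_labels,
                                             collapse = ","))), con)
  }
  fmt <- paste0("%.", digits, "f")
  cols <- apply(record$samples, 2, function(x) sprintf(fmt, x))
  if (is.null(dim(cols))) cols <- matrix(cols, nrow = 1)
  writeLines(do.call(paste, c(split(cols, col(cols)), list(sep = sep))), con)
  invisible(path)
}

#' Read a synthetic-generator configuration from a YAML file
#'
#' Keys mirror the arguments of [synth_config()]; `tr_trajectory` may be
#' given as `tr_constant: <value>`, `tr_diurnal: {mean, amplitude, period_s}`
#' or `tr_step: {breaks_s, values}`.
#'
#' @param path YAML file path
#' @return a [synth_config()]
#' @export
read_synth_config <- function(path) {
  y <- yaml::read_yaml(path)
  traj <- NULL
  if (!is.null(y$tr_constant)) traj <- tr_constant(y$tr_constant)
  if (!is.null(y$tr_diurnal)) traj <- do.call(tr_diurnal, y$tr_diurnal)
  if (!is.null(y$tr_step)) traj <- do.call(tr_step, y$tr_step)
  y$tr_constant <- y$tr_diurnal <- y$tr_step <- NULL
  if (!is.null(traj)) y$tr_trajectory <- traj
  keep <- intersect(names(y), names(formals(synth_config)))
  do.call(synth_config, y[keep])
}
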