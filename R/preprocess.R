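#' Segment-conditioning filter configuration
#'
#' Settings for the three conditioning stages applied to every 10-s
#' segment, in order: baseline-drift removal (two-stage running-median
#' baseline estimate, subtracted), adaptive band-stop suppression of mains
#' interference (notch placed at the periodogram peak within a search band
#' around 50 Hz), and a zero-phase low-pass for residual high-frequency
#' noise.
#'
#' @param drift_windows_ms the two running-median window lengths; the first
#'   (~QRS-length) removes the QRS complex from the baseline estimate, the
#'   second (~T-length) removes P/T waves
#' @param notch_hz nominal mains frequency (default 50)
#' @param notch_q quality factor of the IIR notch (bandwidth = f0/Q)
#' @param adapt_band_hz search band in which the actual interference
#'   frequency is located from the periodogram
#' @param lowpass_hz,lowpass_order Butterworth low-pass cutoff and order
#'   (applied forward-backward, so zero phase and doubled order)
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(drift_windows_ms = c(200, 600),
                          notch_hz = 50, notch_q = 30,
                          adapt_band_hz = c(45, 55),
                          lowpass_hz = 40, lowpass_order = 4) {
  stop_if_not(all(drift_windows_ms > 0), "drift windows must be positive")
  stop_if_not(notch_hz >= adapt_band_hz[1] && notch_hz <= adapt_band_hz[2],
              "notch_hz must lie within adapt_band_hz")
  stop_if_not(lowpass_hz > 0, "low-pass cutoff must be positive")
  structure(list(drift_windows_ms = drift_windows_ms, notch_hz = notch_hz,
                 notch_q = notch_q, adapt_band_hz = adapt_band_hz,
                 lowpass_hz = lowpass_hz, lowpass_order = lowpass_order),
            class = "filter_config")
}

seg_samples <- function(x) if (inherits(x, "ecg_segment")) x$samples else x

seg_rewrap <- function(x, samples) {
  if (inherits(x, "ecg_segment")) { x$samples <- samples; x } else samples
}

seg_fs <- function(x, fs) {
  if (inherits(x, "ecg_segment")) x$fs
  else { stop_if_not(!is.null(fs), "fs required for plain numeric input"); fs }
}

# Zero-phase filtering with reflection padding to suppress edge transients.
filtfilt_reflect <- function(filt, a, x, pad = NULL) {
  n <- length(x)
  p <- min(n - 1L, pad %||% max(50L, 3L * max(length(filt), length(a)) * 10L))
  if (p < 1L) return(as.numeric(signal::filtfilt(filt, a, x)))
  xp <- c(2 * x[1] - x[(p + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - p)])
  y <- as.numeric(signal::filtfilt(filt, a, xp))
  y[(p + 1L):(p + n)]
}

#' Remove baseline drift
#'
#' Estimates the baseline by cascading two running medians (window lengths
#' from `config$drift_windows_ms`) and subtracts it.  The cascade passes
#' slow wander while being unaffected by the QRS complex and the P/T waves,
#' so beat amplitudes are preserved.
#'
#' @param x an [ecg_segment] or numeric vector
#' @param config a [filter_config()]
#' @param fs sampling rate, required when `x` is a plain vector
#' @return same type as `x`, filtered; length preserved
#' @export
remove_baseline <- function(x, config = filter_config(), fs = NULL) {
  fs <- seg_fs(x, fs)
  s <- seg_samples(x)
  k1 <- odd_window(config$drift_windows_ms[1] / 1000, fs)
  k2 <- odd_window(config$drift_windows_ms[2] / 1000, fs)
  if (length(s) < max(k1, k2))
    stop("degenerate input: segment shorter than the largest drift window",
         call. = FALSE)
  base <- stats::runmed(stats::runmed(s, k1, endrule = "median"),
                        k2, endrule = "median")
  seg_rewrap(x, s - as.numeric(base))
}

# Periodogram peak frequency within a band; NA when the band holds no power.
periodogram_peak <- function(s, fs, band) {
  n <- length(s)
  sp <- Mod(stats::fft(s - mean(s)))^2
  freqs <- (seq_len(n) - 1) * fs / n
  keep <- freqs >= band[1] & freqs <= band[2] & freqs <= fs / 2
  if (!any(keep) || all(sp[keep] <= 0)) return(NA_real_)
  freqs[keep][which.max(sp[keep])]
}

#' Suppress mains (power-line) interference
#'
#' Adaptive band-stop: the interference frequency is located as the
#' periodogram peak inside `config$adapt_band_hz`, and a second-order IIR
#' notch (quality factor `config$notch_q`) is placed there and applied
#' forward-backward.  When the band holds no distinct power the notch sits
#' at the nominal `config$notch_hz`.
#'
#' @inheritParams remove_baseline
#' @return same type as `x`, filtered
#' @export
remove_powerline <- function(x, config = filter_config(), fs = NULL) {
  fs <- seg_fs(x, fs)
  s <- seg_samples(x)
  stop_if_not(config$notch_hz < fs / 2, "notch centre must be below Nyquist")
  f0 <- periodogram_peak(s, fs, config$adapt_band_hz)
  if (!is.finite(f0)) f0 <- config$notch_hz
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * config$notch_q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  y <- filtfilt_reflect(b, a, s, pad = as.integer(fs))
  out <- seg_rewrap(x, as.numeric(y))
  attr(out, "notch_hz") <- f0
  out
}

#' Remove residual high-frequency noise
#'
#' Zero-phase Butterworth low-pass (`config$lowpass_hz`, order
#' `config$lowpass_order`, applied forward-backward with reflection
#' padding).  R- and T-wave energy lies below the default 40 Hz cutoff, so
#' fiducial amplitudes are essentially unchanged.
#'
#' @inheritParams remove_baseline
#' @return same type as `x`, filtered
#' @export
remove_highfreq <- function(x, config = filter_config(), fs = NULL) {
  fs <- seg_fs(x, fs)
  s <- seg_samples(x)
  stop_if_not(config$lowpass_hz < fs / 2, "low-pass cutoff must be below Nyquist")
  bf <- signal::butter(config$lowpass_order, config$lowpass_hz / (fs / 2),
                       type = "low")
  y <- filtfilt_reflect(bf$b, bf$a, s, pad = as.integer(fs))
  seg_rewrap(x, as.numeric(y))
}

#' Condition a segment (all three stages, in order)
#'
#' Baseline-drift removal, then adaptive mains notch, then low-pass.
#' Deterministic and length-preserving.
#'
#' @inheritParams remove_baseline
#' @return same type as `x`, conditioned
#' @export
preprocess_segment <- function(x, config = filter_config(), fs = NULL) {
  x <- remove_baseline(x, config, fs)
  x <- remove_powerline(x, config, fs)
  remove_highfreq(x, config, fs)
}
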