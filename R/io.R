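#' S-ICD sensing-vector labels
#'
#' The three Holter channels are surrogates of the three S-ICD sensing
#' vectors: channel A maps to the primary vector, channel B to the
#' alternate, channel C to the secondary.
#'
#' @return `c("primary", "alternate", "secondary")`
#' @export
vector_labels <- function() c("primary", "alternate", "secondary")

#' Multichannel ECG recording
#'
#' Container for a sampled multichannel ECG: a samples matrix
#' (time x channels, mV), the sampling rate and the channel-to-vector
#' labels.  Duration is derived as `n_samples / sampling_rate_hz`.
#'
#' @param samples numeric matrix, one column per channel, or a numeric
#'   vector for a single channel
#' @param sampling_rate_hz sampling rate in Hz
#' @param channel_labels character labels, unique, conventionally drawn from
#'   [vector_labels()]
#' @return An object of class `ecg_record` with fields `samples`,
#'   `sampling_rate_hz`, `channel_labels`, `duration_s`.
#' @export
ecg_record <- function(samples, sampling_rate_hz = 500,
                       channel_labels = NULL) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  stop_if_not(is.matrix(samples) && is.numeric(samples),
              "samples must be a numeric matrix (time x channels)")
  stop_if_not(sampling_rate_hz > 0, "sampling_rate_hz must be positive")
  if (is.null(channel_labels))
    channel_labels <- vector_labels()[seq_len(ncol(samples))]
  stop_if_not(length(channel_labels) == ncol(samples),
              "one label per channel required")
  stop_if_not(!anyDuplicated(channel_labels), "channel labels must be unique")
  colnames(samples) <- channel_labels
  structure(list(samples = samples,
                 sampling_rate_hz = sampling_rate_hz,
                 channel_labels = channel_labels,
                 duration_s = nrow(samples) / sampling_rate_hz),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %d channel(s) [%s], %.6g s at %g Hz (%d samples)\n",
              ncol(x$samples), paste(x$channel_labels, collapse = ", "),
              x$duration_s, x$sampling_rate_hz, nrow(x$samples)))
  invisible(x)
}

#' Read a multichannel ECG from plain-text ASCII
#'
#' Parses the dialect written by [write_ascii()]: optional `#`-prefixed
#' header lines (`# fs=...`, `# channels=...`) followed by one row per
#' sample, tab-, comma- or whitespace-separated numeric columns (mV).
#' Header-declared metadata overrides the arguments.
#'
#' @param path input file
#' @param sampling_rate_hz sampling rate assumed when no header declares one
#' @param channel_labels labels assumed when no header declares them;
#'   defaults to [vector_labels()] in file column order (Holter channels
#'   A, B, C)
#' @return an [ecg_record]
#' @export
read_ascii <- function(path, sampling_rate_hz = 500, channel_labels = NULL) {
  stop_if_not(file.exists(path), paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^\\s*#", lines)
  for (h in lines[hdr]) {
    kv <- sub("^\\s*#\\s*", "", h)
    if (grepl("^fs\\s*=", kv))
      sampling_rate_hz <- as.numeric(sub("^fs\\s*=\\s*", "", kv))
    if (grepl("^channels\\s*=", kv))
      channel_labels <- trimws(strsplit(sub("^channels\\s*=\\s*", "", kv),
                                        ",")[[1]])
  }
  data_lines <- lines[!hdr & nzchar(trimws(lines))]
  if (length(data_lines) == 0)
    stop("empty input: no data rows in '", path, "'", call. = FALSE)
  toks <- strsplit(trimws(data_lines), "[,\t ]+")
  ncols <- lengths(toks)
  if (length(unique(ncols)) != 1)
    stop(sprintf("format error: ragged rows (row %d has %d columns, expected %d)",
                 which(ncols != ncols[1])[1], ncols[which(ncols != ncols[1])[1]],
                 ncols[1]), call. = FALSE)
  nc <- ncols[1]
  if (nc > 3 && is.null(channel_labels))
    stop("configuration error: more than 3 columns requires explicit channel_labels",
         call. = FALSE)
  vals <- suppressWarnings(as.numeric(unlist(toks, use.names = FALSE)))
  bad <- !is.finite(vals)
  if (any(bad)) {
    row <- (which(bad)[1] - 1L) %/% nc + 1L
    stop(sprintf("format error: non-numeric value in data row %d ('%s')",
                 row, data_lines[row]), call. = FALSE)
  }
  samples <- matrix(vals, ncol = nc, byrow = TRUE)
  if (is.null(channel_labels)) channel_labels <- vector_labels()[seq_len(nc)]
  ecg_record(samples, sampling_rate_hz = sampling_rate_hz,
             channel_labels = channel_labels)
}

#' One 10-second single-channel window of a recording
#'
#' @param samples numeric vector of samples (mV)
#' @param fs sampling rate in Hz
#' @param index 0-based position of the window in time order
#' @param channel channel / vector label
#' @param start_s window start time in seconds
#' @return an object of class `ecg_segment`
#' @export
ecg_segment <- function(samples, fs, index = 0L, channel = NA_character_,
                        start_s = index * length(samples) / fs) {
  structure(list(samples = as.numeric(samples), fs = fs,
                 index = as.integer(index), channel = channel,
                 start_s = start_s),
            class = "ecg_segment")
}

#' @export
print.ecg_segment <- function(x, ...) {
  cat(sprintf("<ecg_segment> #%d (%s), %g s at %g Hz, t0=%g s\n",
              x$index, x$channel, length(x$samples) / x$fs, x$fs, x$start_s))
  invisible(x)
}

#' Split a recording into fixed-length segments
#'
#' Cuts each channel into non-overlapping, contiguous windows of exactly
#' `window_s * sampling_rate_hz` samples, indexed from 0 in time order.
#' A trailing partial window is discarded (the screening denominator of
#' 8640 segments per 24 h assumes full 10-s windows only); a record shorter
#' than one window yields an empty list.
#'
#' @param record an [ecg_record]
#' @param window_s window length in seconds (default 10)
#' @return A named list (one element per channel label), each a list of
#'   [ecg_segment] objects.
#' @examples
#' rec <- ecg_record(matrix(rnorm(3 * 12500), ncol = 3), 500)
#' lengths(segment_record(rec))  # 2 segments per channel, 5 s discarded
#' @export
segment_record <- function(record, window_s = 10) {
  stop_if_not(inherits(record, "ecg_record"), "record must be an ecg_record")
  stop_if_not(window_s > 0, "window_s must be positive")
  fs <- record$sampling_rate_hz
  w <- as.integer(round(window_s * fs))
  n_seg <- nrow(record$samples) %/% w
  out <- lapply(seq_along(record$channel_labels), function(c) {
    lab <- record$channel_labels[c]
    lapply(seq_len(n_seg), function(i) {
      ecg_segment(record$samples[((i - 1L) * w + 1L):(i * w), c],
                  fs = fs, index = i - 1L, channel = lab,
                  start_s = (i - 1L) * window_s)
    })
  })
  names(out) <- record$channel_labels
  out
}
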