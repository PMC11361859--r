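#' Per-segment T:R series
#'
#' Tidy container for estimated T:R ratios: one row per (segment, channel),
#' with a validity flag (FALSE when too few beats could be measured or the
#' segment was degenerate) and the estimator that produced it.
#'
#' @param segment integer segment indices (0-based)
#' @param tr estimated T:R values (NA where invalid)
#' @param channel vector label(s)
#' @param valid logical validity flags
#' @param estimator `"oracle"` (rule-based fiducial measurement) or
#'   `"model"` (PSR-image regressor)
#' @return a tibble of class `tr_series`
#' @export
tr_series <- function(segment, tr, channel = NA_character_, valid = !is.na(tr),
                      estimator = c("oracle", "model")) {
  estimator <- match.arg(estimator)
  stop_if_not(all(tr[valid & !is.na(tr)] >= 0), "valid T:R values must be >= 0")
  out <- tibble::tibble(segment = as.integer(segment), channel = channel,
                        tr = as.numeric(tr), valid = valid,
                        estimator = estimator)
  class(out) <- c("tr_series", class(out))
  out
}

#' Detect beats and measure R/T amplitudes in a conditioned segment
#'
#' R peaks are found with an energy detector: the segment is band-passed to
#' the QRS band (5-25 Hz), squared, integrated over a 150 ms moving window,
#' and candidate beats are taken where the energy envelope exceeds an
#' adaptive threshold, with a 300 ms refractory period.  Each candidate is
#' refined to the local signal maximum.  Amplitudes are measured from a
#' local isoelectric baseline (median of the 80 ms window ending 50 ms
#' before the R peak, i.e. just before QRS onset), matching manual caliper
#' practice.  The T peak is the largest absolute deflection from that
#' baseline in the window from 80 ms after R to `min(400 ms, 0.6 * RR)`.
#' Beats closer than 300 ms to their predecessor are discarded.
#'
#' @param segment an [ecg_segment] or numeric vector (already conditioned;
#'   see [preprocess_segment()])
#' @param fs sampling rate, required for plain vectors
#' @param min_beats fewer accepted beats than this flags the segment
#'   invalid (attribute `valid = FALSE`), it is not an error
#' @return A data.frame with one row per accepted beat: `r_time_s`,
#'   `r_amp_mv`, `t_time_s`, `t_amp_mv`, `tr`; attribute `valid`.
#' @export
detect_beats <- function(segment, fs = NULL, min_beats = 5L) {
  fs <- seg_fs(segment, fs)
  x <- seg_samples(segment)
  n <- length(x)
  empty <- data.frame(r_time_s = numeric(0), r_amp_mv = numeric(0),
                      t_time_s = numeric(0), t_amp_mv = numeric(0),
                      tr = numeric(0))
  attr(empty, "valid") <- FALSE
  if (n < fs || stats::sd(x) == 0) return(empty)

  bf <- signal::butter(3, c(5, 25) / (fs / 2), type = "pass")
  xf <- filtfilt_reflect(bf$b, bf$a, x, pad = as.integer(fs / 2))
  env <- as.numeric(stats::filter(xf^2, rep(1 / round(0.15 * fs), round(0.15 * fs)),
                                  sides = 2))
  env[is.na(env)] <- 0
  thr <- 0.25 * stats::quantile(env, 0.99, names = FALSE)
  if (!is.finite(thr) || thr <= 0) return(empty)

  above <- env > thr
  # one candidate per contiguous supra-threshold run, then a refractory pass
  d <- diff(c(FALSE, above, FALSE))
  starts <- which(d == 1); ends <- which(d == -1) - 1L
  cand <- mapply(function(s, e) s - 1L + which.max(env[s:e]), starts, ends)
  cand <- sort(cand)
  keep <- logical(length(cand))
  last <- -Inf
  for (i in seq_along(cand)) {
    if ((cand[i] - last) / fs >= 0.3) { keep[i] <- TRUE; last <- cand[i] }
  }
  cand <- cand[keep]
  # refine to the local maximum of the conditioned signal
  half <- round(0.06 * fs)
  r_idx <- unique(vapply(cand, function(i) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    as.integer(lo - 1 + which.max(x[lo:hi]))
  }, integer(1)))
  r_idx <- sort(r_idx)
  if (length(r_idx) > 1) {
    ok <- c(TRUE, diff(r_idx) / fs >= 0.3)
    r_idx <- r_idx[ok]
  }

  rows <- lapply(seq_along(r_idx), function(k) {
    ri <- r_idx[k]
    b_lo <- ri - round(0.13 * fs); b_hi <- ri - round(0.05 * fs)
    if (b_hi < 1L) return(NULL)
    b_lo <- max(1L, b_lo)
    if (b_hi - b_lo < round(0.02 * fs)) return(NULL)
    baseline <- stats::median(x[b_lo:b_hi])
    r_amp <- x[ri] - baseline
    if (!is.finite(r_amp) || r_amp <= 0) return(NULL)
    rr_next <- if (k < length(r_idx)) (r_idx[k + 1] - ri) / fs
               else if (length(r_idx) > 1) stats::median(diff(r_idx)) / fs
               else 0.8
    t_lo <- ri + round(0.08 * fs)
    t_hi <- ri + round(min(0.4, 0.6 * rr_next) * fs)
    t_hi <- min(n, t_hi)
    if (t_hi - t_lo < round(0.05 * fs)) return(NULL)
    win <- x[t_lo:t_hi] - baseline
    ti <- which.max(abs(win))
    data.frame(r_time_s = (ri - 1) / fs, r_amp_mv = r_amp,
               t_time_s = (t_lo + ti - 2) / fs, t_amp_mv = abs(win[ti]),
               tr = abs(win[ti]) / r_amp)
  })
  beats <- do.call(rbind, rows)
  if (is.null(beats)) beats <- empty
  attr(beats, "valid") <- nrow(beats) >= min_beats
  beats
}

#' Rule-based (oracle) T:R of one segment
#'
#' The segment's T:R is the median of the per-beat ratios from
#' [detect_beats()] — the rule-based surrogate of manual caliper
#' measurement used to validate and label the image regressor.  Robust to a
#' single mis-detected T wave by construction.
#'
#' @param segment an [ecg_segment] or numeric vector, or a beats data.frame
#'   already returned by [detect_beats()]
#' @param fs sampling rate for plain vectors
#' @param min_beats see [detect_beats()]
#' @return A single T:R value, or `NA` with attribute `valid = FALSE` when
#'   too few beats were measurable.
#' @export
oracle_tr <- function(segment, fs = NULL, min_beats = 5L) {
  beats <- if (is.data.frame(segment)) segment
           else detect_beats(segment, fs, min_beats)
  valid <- isTRUE(attr(beats, "valid")) ||
    (is.data.frame(segment) && nrow(beats) >= min_beats)
  if (!valid || nrow(beats) == 0) {
    out <- NA_real_
    attr(out, "valid") <- FALSE
    return(out)
  }
  out <- stats::median(beats$tr)
  attr(out, "valid") <- TRUE
  out
}

#' Estimate T:R for many segments with the rule-based oracle
#'
#' Optionally conditions each segment first, then applies [oracle_tr()].
#'
#' @param segments list of [ecg_segment] (one channel), or the per-channel
#'   list from [segment_record()]
#' @param filter_config a [filter_config()]; `NULL` skips conditioning
#' @param min_beats see [detect_beats()]
#' @return a [tr_series] (rows from all channels when given the per-channel
#'   list)
#' @export
estimate_tr_oracle <- function(segments, filter_config = sicdscreen::filter_config(),
                               min_beats = 5L) {
  if (length(segments) && is.list(segments[[1]]) &&
      !inherits(segments[[1]], "ecg_segment")) {
    parts <- lapply(segments, estimate_tr_oracle,
                    filter_config = filter_config, min_beats = min_beats)
    out <- do.call(rbind, parts)
    class(out) <- c("tr_series", class(tibble::tibble()))
    return(out)
  }
  vals <- vapply(segments, function(s) {
    if (!is.null(filter_config)) s <- preprocess_segment(s, filter_config)
    as.numeric(oracle_tr(s, min_beats = min_beats))
  }, numeric(1))
  tr_series(segment = vapply(segments, function(s) s$index, integer(1)),
            tr = vals,
            channel = vapply(segments, function(s) s$channel, character(1)),
            valid = !is.na(vals), estimator = "oracle")
}

#' Regression error metrics
#'
#' @param predictions,truths equal-length numeric vectors
#' @return list with `mse`, `rmse` (= sqrt(mse)), `mae` and `n`
#' @export
evaluate <- function(predictions, truths) {
  stop_if_not(length(predictions) == length(truths) && length(truths) >= 1,
              "predictions and truths must be non-empty and of equal length")
  err <- predictions - truths
  mse <- mean(err^2)
  list(mse = mse, rmse = sqrt(mse), mae = mean(abs(err)),
       n = length(truths))
}

# Seeded fold assignment stratified by label quantile: labels are ranked and
# consecutive rank blocks of size `folds` each contribute one sample to every
# fold (block-wise shuffled), so all folds span the label range.
stratified_folds <- function(labels, folds, seed) {
  n <- length(labels)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  ord <- order(labels, stats::runif(n))
  fold <- integer(n)
  for (start in seq(1, n, by = folds)) {
    blk <- ord[start:min(start + folds - 1, n)]
    fold[blk] <- sample.int(folds)[seq_along(blk)]
  }
  fold
}

#' Train the PSR-image T:R regressor with cross-validation
#'
#' Runs seeded, label-quantile-stratified k-fold cross-validation of the
#' compact convolutional regressor ([model_spec()]), reporting MSE, RMSE
#' and MAE per fold and pooled over all held-out predictions, then refits
#' the model on all data.
#'
#' @param images list of `psr_image`, or an image matrix from
#'   [images_to_matrix()]
#' @param labels numeric T:R labels (from [oracle_tr()] or synthetic ground
#'   truth); non-finite labels and their images are dropped
#' @param spec a [model_spec()]
#' @param refit refit on all data after cross-validation (default TRUE)?
#'   Otherwise the last fold's model is returned.
#' @return A list of class `tr_fit`: `model` (a `tr_model`), `metrics`
#'   (list with `per_fold` tibble, `pooled` list, `predictions` tibble).
#' @export
train_model <- function(images, labels, spec = model_spec(), refit = TRUE) {
  X <- if (is.matrix(images)) images else images_to_matrix(images)
  keep <- is.finite(labels)
  X <- X[keep, , drop = FALSE]; y <- labels[keep]
  n <- length(y)
  if (n < spec$folds)
    stop("configuration error: fewer labelled images (", n,
         ") than folds (", spec$folds, ")", call. = FALSE)
  if (n < 10 * spec$folds)
    warning("fewer than 10 x folds labelled images; fold metrics will be noisy")
  fold <- stratified_folds(y, spec$folds, spec$seed)
  preds <- rep(NA_real_, n)
  per_fold <- vector("list", spec$folds)
  model <- NULL
  for (f in seq_len(spec$folds)) {
    tr <- fold != f
    sp <- spec; sp$seed <- spec$seed + f
    model <- fit_cnn(X[tr, , drop = FALSE], y[tr], sp)
    preds[!tr] <- predict(model, X[!tr, , drop = FALSE])
    m <- evaluate(preds[!tr], y[!tr])
    per_fold[[f]] <- tibble::tibble(fold = f, n = m$n, mse = m$mse,
                                    rmse = m$rmse, mae = m$mae)
  }
  pooled <- evaluate(preds, y)
  if (refit) model <- fit_cnn(X, y, spec)
  structure(list(
    model = model,
    metrics = list(per_fold = do.call(rbind, per_fold), pooled = pooled,
                   predictions = tibble::tibble(i = which(keep), fold = fold,
                                                truth = y, pred = preds))),
    class = "tr_fit")
}

#' @export
print.tr_fit <- function(x, ...) {
  p <- x$metrics$pooled
  cat(sprintf(
    "<tr_fit> %d-fold CV on %d images: pooled MSE %.4g, RMSE %.4g, MAE %.4g\n",
    x$model$spec$folds, p$n, p$mse, p$rmse, p$mae))
  invisible(x)
}

#' Predict a T:R series from PSR images
#'
#' @param model a `tr_model` (or a `tr_fit`, whose model is used)
#' @param images list of `psr_image`
#' @return a [tr_series] with `estimator = "model"`; images from flat
#'   (degenerate) segments are flagged invalid
#' @export
predict_tr <- function(model, images) {
  if (inherits(model, "tr_fit")) model <- model$model
  X <- images_to_matrix(images)
  preds <- predict(model, X)
  flat <- vapply(images, function(im) isTRUE(im$flat), logical(1))
  tr_series(segment = vapply(images, function(im) im$index, integer(1)),
            tr = ifelse(flat, NA_real_, preds),
            channel = vapply(images, function(im) im$channel, character(1)),
            valid = !flat, estimator = "model")
}

#' Save / load a model checkpoint
#'
#' The checkpoint holds the weights, the [model_spec()] and the input grid
#' size; `write_metrics_csv()` writes the per-fold metrics table.
#'
#' @param model a `tr_model` or `tr_fit`
#' @param fit a `tr_fit`
#' @param path file path
#' @return `path` invisibly; `read_model()` returns the `tr_model`.
#' @export
write_model <- function(model, path) {
  if (inherits(model, "tr_fit")) model <- model$model
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) readRDS(path)

#' @rdname write_model
#' @export
write_metrics_csv <- function(fit, path) {
  m <- if (inherits(fit, "tr_fit")) fit$metrics else fit
  tab <- rbind(as.data.frame(m$per_fold),
               data.frame(fold = NA, n = m$pooled$n, mse = m$pooled$mse,
                          rmse = m$pooled$rmse, mae = m$pooled$mae))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
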