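#' Eligibility rule at the 1:3 cut-off
#'
#' A 10-s segment is unfavourable when its T:R ratio strictly exceeds the
#' threshold (default 1/3, the manual S-ICD screening cut-off); a segment
#' at exactly the threshold is favourable.
#'
#' @param threshold positive T:R cut-off (default 1/3)
#' @return an object of class `eligibility_rule`
#' @export
eligibility_rule <- function(threshold = 1 / 3) {
  stop_if_not(is.numeric(threshold) && threshold > 0,
              "threshold must be positive")
  structure(list(threshold = threshold), class = "eligibility_rule")
}

#' Flag unfavourable segments
#'
#' @param series a [tr_series] (or numeric vector of T:R values)
#' @param rule an [eligibility_rule()]
#' @return logical vector: TRUE where a valid T:R strictly exceeds the
#'   threshold, FALSE where favourable, NA for invalid segments
#' @export
classify_segments <- function(series, rule = eligibility_rule()) {
  if (is.numeric(series)) {
    tr <- series; valid <- !is.na(series)
  } else {
    stop_if_not(nrow(series) >= 1, "series must be non-empty")
    tr <- series$tr; valid <- series$valid & !is.na(series$tr)
  }
  out <- rep(NA, length(tr))
  out[valid] <- tr[valid] > rule$threshold
  out
}

#' Screening failure probability
#'
#' The probability of a vector failing the screening if screened at a
#' random time of day: the number of 10-s segments with unfavourable
#' (T:R > 1:3) ratio divided by the total number of 10-s segments in the
#' recording (8640 for 24 h).
#'
#' @param n_unfavourable count of unfavourable segments
#' @param n_total total segments in the recording
#' @return list with `raw` (the quotient), `rounded` (half-away-from-zero,
#'   2 decimals) and `formatted` (probabilities below 0.005 print as
#'   `"<0.01"`)
#' @examples
#' failure_probability(2450, 8640)$rounded  # 0.28
#' @export
failure_probability <- function(n_unfavourable, n_total) {
  stop_if_not(n_total > 0, "n_total must be positive")
  stop_if_not(n_unfavourable >= 0 && n_unfavourable <= n_total,
              "need 0 <= n_unfavourable <= n_total")
  raw <- n_unfavourable / n_total
  rounded <- round_half_away(raw, 2)
  formatted <- if (raw > 0 && raw < 0.005) "<0.01" else sprintf("%.2f", rounded)
  list(raw = raw, rounded = rounded, formatted = formatted)
}

#' Per-vector screening summary
#'
#' Mean, median and sample SD of the valid T:R values, unfavourable count
#' at the rule's cut-off, and the failure probability.  Following the
#' published screening formula the probability denominator is the total
#' segment count of the recording (invalid segments counted in the
#' denominator, never in the numerator); `denominator = "valid"` restricts
#' it to valid segments instead.
#'
#' @param series a [tr_series] for one vector
#' @param rule an [eligibility_rule()]
#' @param denominator `"total"` (default) or `"valid"`
#' @return one-row tibble: `channel`, `n_segments`, `n_valid`,
#'   `n_unfavourable`, `probability`, `probability_formatted`, `mean_tr`,
#'   `median_tr`, `sd_tr`
#' @export
summarize_vector <- function(series, rule = eligibility_rule(),
                             denominator = c("total", "valid")) {
  denominator <- match.arg(denominator)
  stop_if_not(nrow(series) >= 1, "series must be non-empty")
  flags <- classify_segments(series, rule)
  n_total <- nrow(series)
  n_valid <- sum(!is.na(flags))
  n_unf <- sum(flags, na.rm = TRUE)
  denom <- if (denominator == "total") n_total else n_valid
  p <- if (denom > 0) failure_probability(n_unf, denom)
       else list(raw = NA_real_, formatted = NA_character_)
  vals <- series$tr[series$valid & !is.na(series$tr)]
  tibble::tibble(
    channel = series$channel[1],
    n_segments = n_total, n_valid = n_valid, n_unfavourable = n_unf,
    probability = p$raw, probability_formatted = p$formatted,
    mean_tr = if (n_valid) mean(vals) else NA_real_,
    median_tr = if (n_valid) stats::median(vals) else NA_real_,
    sd_tr = if (n_valid > 1) stats::sd(vals) else NA_real_)
}

#' Screen a whole recording
#'
#' Convenience wrapper: summarizes a multi-vector [tr_series] (as returned
#' by [estimate_tr_oracle()] or [predict_tr()]) into one row per vector.
#'
#' @inheritParams summarize_vector
#' @return tibble with one [summarize_vector()] row per channel
#' @export
screen_series <- function(series, rule = eligibility_rule(),
                          denominator = c("total", "valid")) {
  denominator <- match.arg(denominator)
  parts <- lapply(split(series, series$channel), function(s) {
    class(s) <- class(series)
    summarize_vector(s, rule, denominator)
  })
  out <- do.call(rbind, parts)
  out[order(match(out$channel, vector_labels())), ]
}

#' Cohort mean and SD of per-patient failure probabilities
#'
#' Summarizes per-patient failure probabilities (or their unfavourable
#' segment counts) for one vector of one cohort: arithmetic mean and sample
#' SD of the probabilities, both rounded half-away-from-zero to 2 decimals,
#' plus the mean unfavourable-segment count.
#'
#' @param counts per-patient unfavourable segment counts
#' @param n_total per-recording total segment count (8640 for 24 h)
#' @param probabilities alternatively, per-patient probabilities directly
#' @return list with `mean`, `sd` (2-dp rounded), `mean_raw`, `sd_raw`,
#'   `mean_count` (rounded to integer, NA when counts not given) and `n`
#' @examples
#' group_failure_means(c(2450, 7106, 0, 7488, 1411, 0), 8640)$mean  # 0.36
#' @export
group_failure_means <- function(counts = NULL, n_total = 8640,
                                probabilities = NULL) {
  if (is.null(probabilities)) {
    stop_if_not(!is.null(counts), "supply counts or probabilities")
    probabilities <- counts / n_total
  }
  n <- length(probabilities)
  stop_if_not(n >= 1, "empty cohort")
  m <- mean(probabilities)
  s <- if (n > 1) stats::sd(probabilities) else NA_real_
  list(mean = round_half_away(m, 2),
       sd = if (is.na(s)) NA_real_ else round_half_away(s, 2),
       mean_raw = m, sd_raw = s,
       mean_count = if (is.null(counts)) NA_real_
                    else round_half_away(mean(counts), 0),
       n = n)
}

#' Welch two-sample t-test
#'
#' Unequal-variance two-sample t-test with Welch-Satterthwaite degrees of
#' freedom, two-sided, with a 95% confidence interval for the difference in
#' means — the comparison used for all cohort contrasts.
#'
#' @param group_a,group_b numeric vectors, each with at least two finite
#'   values
#' @param parameter optional name of the compared quantity (carried in the
#'   output)
#' @return list of class `group_comparison`: `parameter`, `n_a`, `n_b`,
#'   `mean_a`, `mean_b`, `sd_a`, `sd_b`, `t`, `df`, `p_value`, `conf_int`
#'   (a-minus-b, 95%)
#' @export
welch_test <- function(group_a, group_b, parameter = NA_character_) {
  stop_if_not(sum(is.finite(group_a)) >= 2 && sum(is.finite(group_b)) >= 2,
              "each group needs at least two finite values")
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE,
                      conf.level = 0.95)
  structure(list(parameter = parameter,
                 n_a = length(group_a), n_b = length(group_b),
                 mean_a = mean(group_a), mean_b = mean(group_b),
                 sd_a = stats::sd(group_a), sd_b = stats::sd(group_b),
                 t = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value, conf_int = as.numeric(ht$conf.int)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison>%s t = %.4g, df = %.4g, p = %.4g, 95%% CI (%.4g, %.4g)\n",
    if (is.na(x$parameter)) "" else paste0(" ", x$parameter, ":"),
    x$t, x$df, x$p_value, x$conf_int[1], x$conf_int[2]))
  invisible(x)
}

#' Compare cohorts on several T:R summary parameters
#'
#' Applies [welch_test()] to each shared column of two per-vector (or
#' per-patient) summary tables, e.g. the outputs of [screen_series()]
#' stacked over subjects.
#'
#' @param summary_a,summary_b data frames with numeric summary columns
#' @param parameters column names to compare (default: mean/median/SD of
#'   T:R and the failure probability, where present)
#' @return tibble: parameter, group means/SDs, t, df, p_value, CI bounds
#' @export
compare_groups <- function(summary_a, summary_b,
                           parameters = intersect(
                             c("mean_tr", "median_tr", "sd_tr", "probability"),
                             intersect(names(summary_a), names(summary_b)))) {
  rows <- lapply(parameters, function(p) {
    w <- welch_test(summary_a[[p]], summary_b[[p]], parameter = p)
    tibble::tibble(parameter = p, n_a = w$n_a, n_b = w$n_b,
                   mean_a = w$mean_a, sd_a = w$sd_a,
                   mean_b = w$mean_b, sd_b = w$sd_b,
                   t = w$t, df = w$df, p_value = w$p_value,
                   ci_lo = w$conf_int[1], ci_hi = w$conf_int[2])
  })
  do.call(rbind, rows)
}

#' Plot the T:R variation over the recording
#'
#' Time on the x-axis, estimated T:R on the y-axis, one trace per sensing
#' vector, a horizontal line at the eligibility threshold; invalid segments
#' leave gaps.
#'
#' @param series a [tr_series] (any number of vectors)
#' @param rule an [eligibility_rule()]
#' @param path optional file path; when given the figure is written there
#'   (format from the extension, e.g. `.png`, `.pdf`) and the ggplot object
#'   returned invisibly
#' @param window_s segment length used to place segments in time
#' @return a ggplot object
#' @export
plot_tr_variation <- function(series, rule = eligibility_rule(), path = NULL,
                              window_s = 10) {
  stop_if_not(!is.null(series) && nrow(series) >= 1,
              "empty series: nothing to plot")
  df <- tibble::tibble(
    hours = series$segment * window_s / 3600,
    tr = ifelse(series$valid, series$tr, NA_real_),
    vector = factor(series$channel, levels = vector_labels()))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = hours, y = tr, colour = vector)) +
    ggplot2::geom_line(linewidth = 0.3, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = rule$threshold, linetype = "dashed") +
    ggplot2::labs(x = "Time (h)", y = "T:R ratio", colour = "S-ICD vector") +
    ggplot2::theme_minimal()
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 8, height = 4, dpi = 150)
    return(invisible(p))
  }
  p
}
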