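test_that("the 1:3 cut-off is strict and invalid segments stay missing", {
  ser <- tr_series(segment = 0:3, tr = c(1 / 3, 0.34, 0.1, NA),
                   valid = c(TRUE, TRUE, TRUE, FALSE))
  flags <- classify_segments(ser)
  expect_identical(flags, c(FALSE, TRUE, FALSE, NA))
  # all-invalid series: zero unfavourable, all missing
  inv <- tr_series(segment = 0:2, tr = rep(NA_real_, 3), valid = rep(FALSE, 3))
  expect_true(all(is.na(classify_segments(inv))))
  expect_equal(sum(classify_segments(inv), na.rm = TRUE), 0)
})

test_that("failure probability matches its definition and formatting rules", {
  expect_equal(failure_probability(2450, 8640)$rounded, 0.28)
  expect_equal(failure_probability(0, 8640)$rounded, 0)
  expect_equal(failure_probability(8640, 8640)$rounded, 1)
  expect_equal(failure_probability(34, 8640)$formatted, "<0.01")
  expect_equal(failure_probability(122, 8640)$formatted, "0.01")
  expect_error(failure_probability(1, 0), "positive")
  expect_error(failure_probability(10, 5), "<=")
})

test_that("classify/count/probability equals a brute-force loop on random series", {
  set.seed(33)
  for (rep in 1:10) {
    n <- sample(50:300, 1)
    tr <- runif(n, 0, 0.7)
    valid <- runif(n) > 0.1
    tr[!valid] <- NA
    thr <- runif(1, 0.1, 0.5)
    ser <- tr_series(segment = seq_len(n) - 1, tr = tr, valid = valid)
    rule <- eligibility_rule(thr)
    n_unf <- sum(classify_segments(ser, rule), na.rm = TRUE)
    p <- failure_probability(n_unf, n)$raw
    # brute force
    cnt <- 0
    for (i in seq_len(n)) if (valid[i] && tr[i] > thr) cnt <- cnt + 1
    expect_identical(p, cnt / n)
    # permutation invariance
    perm <- sample(n)
    ser_p <- tr_series(segment = seq_len(n) - 1, tr = tr[perm], valid = valid[perm])
    expect_identical(sum(classify_segments(ser_p, rule), na.rm = TRUE), n_unf)
    # monotonicity: raising the threshold never increases the probability
    p_hi <- sum(classify_segments(ser, eligibility_rule(thr + 0.1)), na.rm = TRUE) / n
    expect_lte(p_hi, p)
  }
})

test_that("vector summaries compute the documented statistics", {
  ser <- tr_series(segment = 0:2, tr = c(0.1, 0.2, 0.3), channel = "primary")
  s <- summarize_vector(ser)
  expect_equal(s$mean_tr, 0.2)
  expect_equal(s$median_tr, 0.2)
  expect_equal(s$sd_tr, 0.1)
  expect_equal(s$n_unfavourable, 0)
  # constant series: SD 0
  sc <- summarize_vector(tr_series(segment = 0:4, tr = rep(0.4, 5)))
  expect_equal(sc$sd_tr, 0)
  expect_equal(sc$probability, 1)  # 0.4 > 1/3 everywhere
  # invalid segments: in the total denominator, never the numerator
  mix <- tr_series(segment = 0:3, tr = c(0.5, 0.5, NA, NA),
                   valid = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(summarize_vector(mix)$probability, 2 / 4)
  expect_equal(summarize_vector(mix, denominator = "valid")$probability, 1)
  # zero valid segments: missing statistics, zero unfavourable
  none <- tr_series(segment = 0:1, tr = c(NA_real_, NA_real_), valid = FALSE)
  sn <- summarize_vector(none)
  expect_true(is.na(sn$mean_tr))
  expect_equal(sn$n_unfavourable, 0)
})

test_that("cohort means from per-patient counts match their definition", {
  g <- group_failure_means(c(2450, 7106, 0, 7488, 1411, 0), 8640)
  expect_equal(g$mean, 0.36)
  expect_equal(g$mean_raw, sum(c(2450, 7106, 0, 7488, 1411, 0)) / (6 * 8640))
  # single patient: mean is that value, SD undefined (flagged NA)
  g1 <- group_failure_means(probabilities = 0.25)
  expect_equal(g1$mean, 0.25)
  expect_true(is.na(g1$sd))
  expect_error(group_failure_means(probabilities = numeric(0)), "empty")
})

test_that("welch_test matches the textbook formula to 1e-10", {
  welch_brute <- function(a, b) {
    m <- mean(a) - mean(b)
    se2 <- var(a) / length(a) + var(b) / length(b)
    t <- m / sqrt(se2)
    df <- se2^2 / ((var(a) / length(a))^2 / (length(a) - 1) +
                   (var(b) / length(b))^2 / (length(b) - 1))
    p <- 2 * pt(-abs(t), df)
    ci <- m + c(-1, 1) * qt(0.975, df) * sqrt(se2)
    list(t = t, df = df, p = p, ci = ci)
  }
  w <- welch_test(c(1, 2, 3), c(1, 2, 3, 4))
  b <- welch_brute(c(1, 2, 3), c(1, 2, 3, 4))
  expect_equal(w$t, b$t, tolerance = 1e-10)
  expect_equal(w$p_value, b$p, tolerance = 1e-10)
  set.seed(12)
  for (rep in 1:10) {
    a <- rnorm(sample(3:20, 1)); bb <- rnorm(sample(3:20, 1), 0.5)
    w <- welch_test(a, bb)
    br <- welch_brute(a, bb)
    expect_equal(w$t, br$t, tolerance = 1e-10)
    expect_equal(w$df, br$df, tolerance = 1e-10)
    expect_equal(w$p_value, br$p, tolerance = 1e-10)
    expect_equal(w$conf_int, br$ci, tolerance = 1e-10)
    # CI excludes 0 iff p < 0.05
    expect_identical(w$p_value < 0.05, !(w$conf_int[1] <= 0 & w$conf_int[2] >= 0))
  }
  # identical groups: t = 0, p = 1
  w0 <- welch_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w0$t, 0)
  expect_equal(w0$p_value, 1)
  expect_error(welch_test(1, c(1, 2)), "at least two")
})

test_that("T:R variation plots are written with threshold line and gaps", {
  set.seed(2)
  ser <- do.call(rbind, lapply(vector_labels(), function(ch) {
    tr_series(segment = 0:99, tr = runif(100, 0.1, 0.6), channel = ch,
              valid = runif(100) > 0.05)
  }))
  class(ser) <- class(tr_series(0, 0.1))
  path <- withr::local_tempfile(fileext = ".png")
  p <- plot_tr_variation(ser, path = path)
  expect_true(file.exists(path) && file.size(path) > 0)
  # plotted data cover both sides of the cut-off, invalid segments gapped
  built <- ggplot2::ggplot_build(p)$data[[1]]
  expect_gt(sum(built$y > 1 / 3, na.rm = TRUE), 0)
  expect_gt(sum(built$y < 1 / 3, na.rm = TRUE), 0)
  expect_error(plot_tr_variation(tr_series(integer(0), numeric(0))), "empty")
})

test_that("screen_series summarizes each vector of a multi-channel series", {
  ser <- do.call(rbind, lapply(c(0.2, 0.4, 0.3), function(mu) {
    tr_series(segment = 0:49, tr = rep(mu, 50),
              channel = vector_labels()[which(c(0.2, 0.4, 0.3) == mu)])
  }))
  class(ser) <- class(tr_series(0, 0.1))
  tab <- screen_series(ser)
  expect_equal(tab$channel, vector_labels())
  expect_equal(tab$probability, c(0, 1, 0))
  expect_equal(tab$mean_tr, c(0.2, 0.4, 0.3))
})
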