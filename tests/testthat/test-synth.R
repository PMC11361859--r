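test_that("generated recordings have the configured shape and are deterministic", {
  cfg <- noisy_config(duration_s = 45, seed = 9)
  sim1 <- generate_recording(cfg)
  sim2 <- generate_recording(cfg)
  expect_identical(sim1$record$samples, sim2$record$samples)
  expect_identical(sim1$ground_truth$tr, sim2$ground_truth$tr)
  expect_equal(dim(sim1$record$samples), c(45 * 500, 3))
  expect_equal(sim1$record$channel_labels, vector_labels())
  expect_equal(sim1$record$duration_s, 45)
  # different seed, different noise
  sim3 <- generate_recording(noisy_config(duration_s = 45, seed = 10))
  expect_false(identical(sim1$record$samples, sim3$record$samples))
})

test_that("ground-truth T:R follows the programmed trajectory", {
  # constant template ratio: R = 1.0, T = 0.25 -> every segment 0.25
  sim <- generate_recording(clean_config(duration_s = 60, tr = 0.25))
  expect_true(all(sim$ground_truth$tr$tr == 0.25))
  expect_equal(nrow(sim$ground_truth$tr), 6 * 3)
  # zero T amplitude -> T:R 0 everywhere
  sim0 <- generate_recording(clean_config(duration_s = 30, tr = 0))
  expect_true(all(sim0$ground_truth$tr$tr == 0))
  # step trajectory lands in the right segments
  traj <- tr_step(30, c(0.2, 0.5))
  simst <- generate_recording(clean_config(duration_s = 60, tr = traj))
  gt <- subset(sim$ground_truth$tr, channel == "primary")
  gtst <- subset(simst$ground_truth$tr, channel == "primary")
  expect_equal(gtst$tr, c(0.2, 0.2, 0.2, 0.5, 0.5, 0.5))
  # per-channel T-wave gain scales the truth channel-wise
  simg <- generate_recording(clean_config(duration_s = 30, tr = 0.3,
                                          t_gain = c(1, 0.5, 2)))
  wide <- split(simg$ground_truth$tr$tr, simg$ground_truth$tr$channel)
  expect_equal(unique(wide$alternate / wide$primary), 0.5)
  expect_equal(unique(wide$secondary / wide$primary), 2)
})

test_that("invalid configurations and trajectories are rejected", {
  expect_error(synth_config(duration_s = 0), "duration")
  expect_error(synth_config(sampling_rate_hz = -1), "sampling_rate")
  expect_error(synth_config(white_noise_sd_mv = -0.1), "noise")
  expect_error(generate_recording(clean_config(duration_s = 30, tr = -0.2)),
               "negative")
  expect_error(beat_template(r = c(-1, 0, 0.012)), "R amplitude")
})

test_that("YAML configurations round-trip into synth_config", {
  cfg <- read_synth_config(system.file("extdata", "synth-example.yaml",
                                       package = "sicdscreen"))
  expect_s3_class(cfg, "synth_config")
  expect_equal(cfg$duration_s, 3600)
  expect_equal(cfg$heart_rate_bpm, 65)
  expect_equal(cfg$tr_trajectory(900), 0.40)  # peak of the diurnal swing
  expect_equal(cfg$channel_gain, c(1.0, 0.8, 0.9))
  expect_equal(cfg$rng_seed, 42L)
})

test_that("powerline interference is present raw and removed by conditioning", {
  cfg <- synth_config(duration_s = 20, tr_trajectory = tr_constant(0.3),
                      tr_ar1_sd = 0, baseline_wander_mv = 0,
                      powerline_mv = 0.1, white_noise_sd_mv = 0, rng_seed = 3)
  sim <- generate_recording(cfg)
  seg <- segment_record(sim$record)$primary[[1]]
  peak_raw <- sicdscreen:::periodogram_peak(seg$samples, seg$fs, c(49, 51))
  expect_true(is.finite(peak_raw))  # a spectral peak inside 49-51 Hz
  clean <- preprocess_segment(seg)
  # after conditioning the 50 Hz line is gone: band power drops > 20 dB
  bandpow <- function(x) {
    sp <- Mod(stats::fft(x - mean(x)))^2
    f <- (seq_along(x) - 1) * seg$fs / length(x)
    sum(sp[f >= 49 & f <= 51])
  }
  expect_lt(bandpow(clean$samples), bandpow(seg$samples) / 100)
})

test_that("ASCII round-trip preserves shape, metadata and samples", {
  sim <- generate_recording(noisy_config(duration_s = 10, seed = 2))
  path <- withr::local_tempfile(fileext = ".txt")
  write_ascii(sim$record, path)
  lines <- readLines(path)
  expect_equal(sum(!grepl("^#", lines)), 5000)
  rec2 <- read_ascii(path)
  expect_equal(rec2$sampling_rate_hz, 500)
  expect_equal(rec2$channel_labels, vector_labels())
  expect_lt(max(abs(rec2$samples - sim$record$samples)), 1e-6)
  # empty record refuses to write
  expect_error(write_ascii(ecg_record(matrix(numeric(0), ncol = 1)), path),
               "empty")
})
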