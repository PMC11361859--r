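# Shared fixture builders: short, seeded synthetic recordings.

clean_config <- function(duration_s = 60, tr = 0.3, seed = 1, ...) {
  synth_config(duration_s = duration_s,
               tr_trajectory = if (is.function(tr)) tr else tr_constant(tr),
               tr_ar1_sd = 0, baseline_wander_mv = 0, powerline_mv = 0,
               white_noise_sd_mv = 0, rng_seed = seed, ...)
}

noisy_config <- function(duration_s = 60, tr = 0.3, seed = 1, ...) {
  synth_config(duration_s = duration_s,
               tr_trajectory = if (is.function(tr)) tr else tr_constant(tr),
               tr_ar1_sd = 0, rng_seed = seed, ...)
}

# one clean conditioned segment with a programmed T:R, for fiducial tests
clean_segment <- function(tr = 0.3, seed = 1, channel = "primary") {
  sim <- generate_recording(clean_config(duration_s = 20, tr = tr, seed = seed))
  segment_record(sim$record)[[channel]][[1]]
}
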