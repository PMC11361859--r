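# Example synthetic-Holter configuration: one hour at 500 Hz with a
# diurnal-style T:R swing around 0.30 and moderate noise on all channels.
duration_s: 3600
sampling_rate_hz: 500
heart_rate_bpm: 65
rr_jitter_sd_s: 0.04
tr_diurnal:
  mean: 0.30
  amplitude: 0.10
  period_s: 3600
tr_ar1_sd: 0.01
tr_ar1_phi: 0.9
channel_gain: [1.0, 0.8, 0.9]
t_gain: [1.0, 1.0, 1.0]
baseline_wander_mv: 0.15
baseline_wander_hz: 0.25
powerline_mv: 0.05
powerline_hz: 50
white_noise_sd_mv: 0.02
rng_seed: 42
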