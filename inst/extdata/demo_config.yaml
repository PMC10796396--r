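# Compact demo configuration for `intake-fuse demo` / run_pipeline().
# One synthetic hour-and-a-bit per day, three eating episodes separated by
# more than 15 minutes, image false-positive rate 20%.
seed: 7
simulate_train:
  duration_s: 3800
  n_episodes: 3
  episode_duration_range_s: [90, 200]
  inter_episode_gap_range_s: [920, 1000]
  chew_amplitude: 0.2
  noise_amplitude: 0.02
simulate_eval:
  duration_s: 3800
  n_episodes: 3
  episode_duration_range_s: [90, 200]
  inter_episode_gap_range_s: [920, 1000]
  chew_amplitude: 0.2
  noise_amplitude: 0.02
scores:
  fp_rate: 0.2
sensor:
  epochs: 8
fusion:
  n_lags: 1
episodes:
  gap_min: 15
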