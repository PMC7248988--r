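# Demo session: 10 minutes, latent fatigue stepping from rested (0) to
# fatigued (1) mid-session, KSS 2 -> 4.  All seeds explicit.
seed: 42
duration: 600
rate: 128
subject_id: S01
kss_pre: 2
kss_post: 4
profile:
  times: [0, 280, 320, 600]
  levels: [0, 0, 1, 1]
generator:
  heart_rate_low: 70
  heart_rate_high: 60
  emg_amplitude_low: 1.0
  emg_amplitude_high: 0.5
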