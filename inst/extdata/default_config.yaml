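# Default pipeline configuration. Every protocol constant of the analysis
# lives here, not in code.
seed: 1
n_subjects: 4
simulate:
  n_trials: {AI: 10, AT: 10, S40: 10, S60: 10, S80: 10}
  fs_native: 3000
  iti_s: 4            # compressed inter-trial gap; behavioural protocol used 120
  pink_exponent: 1
  pink_rms_uV: 12
  mains_amp_uV: 10
  drift_uV_per_s: 2
  artifact_spike_ratio: 12
  tail_amp_uV: 80
  tail_tau_ms: 5
  turn_duration_mean_s: 1.961
  turn_duration_sd_s: 0.201
  turn_duration_min_s: 0.5
stimulation:
  frequencies_hz: [40, 60, 80]
  pulse_width_ms: 1
  duration_s: 2
artifact:
  threshold_k: 8
  tail_window_ms: 20
  min_tails: 10
  pad_s: 0.05
  subtract_tail: true
preprocess:
  fs_out: 512
  bandpass_hz: [1, 200]
  notch_hz: 50
  rejection_ratio: 5
spectral:
  bands:
    A: [0.5, 3]
    B: [4, 12]
    C: [13, 60]
    D: [61, 130]
    E: [131, 200]
  phase: during
  epoch_len_s: 2
stats:
  alpha: 0.05
  gg_policy: mauchly   # or "always"
  significance_marks: {"0.05": "*", "0.01": "**", "0.001": "***"}
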