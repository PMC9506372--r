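# Reference configuration: the default analysis settings of the ITF
# extraction method.  Any field omitted here falls back to the same value in
# default_config(); deviations from these settings are echoed in the report.
preprocess:
  highpass_hz: 0.1
  line_freq_hz: 50
  reject_ptp_uv: 150
  excluded_channels: []
epoch:
  t0_ms: -1000
  t1_ms: 2500
  baseline_ms: [-800, 0]
tfr:
  freq_min_hz: 1
  freq_max_hz: 15
  freq_step_hz: 0.5
  n_cycles: 7
  analysis_min_hz: 2
  trial_norm: average
windows:
  start_ms: 250
  end_ms: 1250
  width_ms: 100
  step_ms: 50
electrodes: [Cz, C3, C4, Pz, P3, P4]
fallback:
  electrodes: [PO7, PO8]
  trigger_theta_share_pct: 20
bands:
  delta: [2, 4]
  theta: [4, 8]
  alpha: [8, 12]
resting:
  epoch_ms: 3500
  baseline_first_ms: 1000
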