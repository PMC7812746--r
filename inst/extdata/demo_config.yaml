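# Demo pipeline configuration: surrogate source with four stimulus
# conditions mirroring the experimental design (air puff, air puff with
# simultaneous or delayed Purkinje stimulation, and baseline), analyzed
# between the deep channel of area 1 and the superficial channel of area 2.
seed: 7
source: surrogate
output_dir: ctcoh_demo_out
surrogate:
  n_channels_per_area: 4
  sampling_rate: 250
  n_trials: 40
  trial_length: 2
  shared_band: [30, 45]
  background_sd: 0.6
  conditions:
    baseline:  {shared_fraction: 0.15}
    AP:        {shared_fraction: 0.60}
    AP_PC:     {shared_fraction: 0.30}
    AP_PC_delay: {shared_fraction: 0.55}
analysis:
  freqs: {lo: 4, hi: 80, n_points: 18}
  cycles: 7
  alpha: 0.05
  channel_x: 4   # deep channel, area 1
  channel_y: 5   # superficial channel, area 2
comparisons:
  - [AP, AP_PC]
  - [AP, AP_PC_delay]
  - [baseline, AP]
  - [baseline, AP_PC]
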