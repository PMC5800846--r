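# Example run configuration for cavesleepr::run_pipeline()
# Paths are resolved relative to this file's directory.
output_dir: out
seed: 1
manifest: manifest.csv          # cohort of trajectory CSVs (see read_manifest)
scoring:
  speed_threshold: 4            # mm/s; frames slower than this are immobile
  smooth_window_s: 1            # rolling-median speed smoothing, seconds
  min_sleep_s: 60               # the sleep criterion: immobility >= 60 s
  min_interrupt_s: 1            # movement shorter than this does not end a bout
  max_gap_s: 1                  # interpolate tracking dropouts up to this span
  bin_minutes: 60               # sleep-profile bin width
photoperiod:
  lights_on_zt: 0
  lights_off_zt: 14             # 14:10 light-dark cycle
  period: 24
stats:
  response: total_sleep_min
  method: t_unpaired            # or rank_nonparametric
  contrasts:
    - ["cavefish:control", "cavefish:antagonist"]
    - ["surface:control", "surface:antagonist"]
qpcr:
  file: qpcr.csv                # long format: sample_id,group,run_id,gene,ct
  target: hcrt
  reference: gapdh
  calibrator_group: surface_control
  calibrator_sample: IRC        # shared inter-run calibrator
cells:
  manifest: stacks.csv          # columns: file,brain_id,group
  threshold_k: 3
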