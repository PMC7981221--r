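# telegaps run configuration (merged over default_config(); only keys you
# change need to appear here)

paths:
  detections: bundle/detections.csv
  receivers: bundle/receivers.csv
  individuals: bundle/individuals.csv
  output_dir: telegaps-out

# column maps let vendor exports load unchanged, e.g. a VEMCO VUE export:
# columns:
#   detections:
#     tag_id: "Transmitter"
#     receiver_id: "Receiver"
#     timestamp: "Date and Time (UTC)"

timezone: "Etc/GMT-6"        # local zone for diel/season (UTC+06:00)

filters:
  min_recursion_gap_s: 360   # recursions shorter than this are dropped
  rdet_max: 5                # transitions faster than 5x expected are dropped

species_params:
  gray_reef:
    swim_speed_m_s: 0.69
  silvertip:
    swim_speed_m_s: 0.73

diel:
  day_start: "07:00"
  night_start: "19:00"

season:
  wet_months: [10, 11, 12, 1, 2, 3]

model:
  fixed: [species, sex, log_size, diel, season]
  interactions_with_species: [sex, log_size, diel, season]
  receiver_role: destination  # grouping receiver for transitions (or: origin)
  vif_threshold: 5
  weight_threshold: 0.9       # report best model alone above this weight
  averaging: full             # zero-substitution; or: natural

crossval:
  train_fraction: 0.8
  seed: 42
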