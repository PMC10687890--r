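out_dir: contact_rsf_run
seed: 1
tracks_csv: ~
env_dir: ~
interval_min: 5.0
buffer_m: 10.0
ratio: 30.0
isopleths:
- 0.95
- 0.5
collinearity_threshold: 0.6
overlap_threshold: 0.5
min_contacts: 10.0
cv_folds: 5.0
cv_bins: 10.0
core_isopleth: 0.5
min_consecutive_weeks: 12.0
candidates: ~
weights_mode: product
predict_date: ~
sim:
  extent_m: 3000.0
  cell_size_m: 30.0
  n_days: 14.0
  n_food_sites: 6.0
  n_groups: 2.0
  animals_per_group: 2.0
  tau_p_min: 60.0
  tau_v_min: 15.0
  sigma_m2: 10000.0
  fix_interval_min: 10.0
  attraction_coeffs:
    food: 1.0986122886681098
  gps_error_sd: 5.0
  visits_per_day: 2.0
  visit_duration_min:
  - 30.0
  - 90.0
  dropout: 0.02
  sex: F
  group_spread: 0.3
log_level: info
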