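# Traffic-light threshold configuration template.
# Keys mirror vsa_thresholds() exactly; pressures in mm Hg, Shock Index
# (pulse / systolic BP) dimensionless.

# Hypertension tiers: a reading is yellow when SBP or DBP reaches the
# yellow threshold, red when either reaches the red threshold.
hyp_yellow_sbp: 140
hyp_yellow_dbp: 90
hyp_red_sbp: 160
hyp_red_dbp: 110

# Shock tiers, on Shock Index = pulse / SBP.
si_yellow: 0.9
si_red: 1.7

# true: a reading exactly at a threshold triggers the tier (>=);
# false: strict comparison (>).
inclusive_boundaries: true

# Display symbols per alerting condition. Shock alerts outrank
# hypertension and use the more urgent symbol. The utility entries
# (low_battery, error) are display-only.
display_map:
  shock: flashing down arrow
  hypertension: constant up arrow
  none: none
  low_battery: battery symbol
  error: error symbol
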