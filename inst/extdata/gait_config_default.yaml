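gait:
  young:
    torso_speed_mean: 1.3
    torso_speed_sd: 0.1
    torso_fluct_amp: 0.3
    cycle_duration_mean: 1.05
    cycle_duration_sd: 0.05
    swing_peak_velocity_mean: 1.7
    swing_peak_velocity_sd: 0.1
    stance_residual_velocity: 0.1
    stance_duty: 0.4
    limb_reflectivities:
      torso: 1.0
      tibia: 0.1
      foot: 0.22
  elderly:
    torso_speed_mean: 1.0
    torso_speed_sd: 0.15
    torso_fluct_amp: 0.3
    cycle_duration_mean: 1.15
    cycle_duration_sd: 0.05
    swing_peak_velocity_mean: 1.4
    swing_peak_velocity_sd: 0.1
    stance_residual_velocity: 0.04
    stance_duty: 0.44
    limb_reflectivities:
      torso: 1.0
      tibia: 0.1
      foot: 0.22
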