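# Default adult-female model configuration.
#
# Values with provenance "paper" are the published defaults of the skin-uptake
# model (permeability, skin partition coefficients, skin volumes and flows,
# modulation schedule, instrument dead space, reference respiratory values).
# Values with provenance "reference-config" are a SYNTHETIC reference set for
# the whole-body circulation backbone (cardiac output, blood pool volumes,
# blood-air partition, per-tissue flow fractions / partitions / volumes),
# assembled from standard adult-female physiology and published radon
# solubility data. They are representative, not a verbatim transcription of
# any single source table, and are freely overridable.
# Values with provenance "assumption" have no published number and are
# documented model choices.
#
# Units are encoded in field names: _per_h (h-1), _l (litre), _m2 (m2),
# _m_per_s (m s-1), _min (minute), _per_d (d-1), _l_per_h (l h-1).
physical:
  lambda_r_per_h: 0.007554        # Rn-222 decay constant, half-life 3.8235 d
blood:
  cardiac_output_l_per_h: 354.0   # 5.9 l min-1, resting adult female
  v_arterial_l: 1.0               # non-pulmonary arterial pool
  v_venous_l: 2.4                 # non-pulmonary venous pool
  p_blood_air: 0.43               # radon blood-air partition coefficient
skin:
  k0_m_per_s: 2.4e-07             # baseline dermal permeability coefficient
  p_sw: 0.4                       # skin-water partition
  p_sa: 0.4                       # skin-air partition (assumed = p_sw)
  p_dsb: 0.4                      # dermal skin - blood partition
  p_ssb: 11.0                     # subcutaneous skin - blood partition
  v_ds_l: 1.84
  v_ss_l: 9.35
  area_m2: 1.66                   # total skin surface area, reference female
  exposed_fraction: 0.9           # fraction of skin immersed in the bath
  k_ds_per_h: 0.18                # dermal <-> subcutaneous transfer coefficient
  flow_fraction_ds: 0.007
  flow_fraction_ss: 0.060
  kappa_dry: 4.0                  # dry-skin permeability multiplier (air contact)
modulation:
  ramp_factor: 4.0                # peak temperature multiplier on K and skin flows
  ramp_end_min: 10.0
  swell_start_min: 12.5
  swell_factor: 2.5               # total reduction of K by stratum-corneum swelling
  swell_end_min: 20.0
  kds_coupling: 0.2               # fractional strength of the modulation on k_DS
  apply_swelling: false
instrument:
  v_dead_l: 0.110                 # instrumental dead space between the valves
  sampling_interval_min: 4.0
respiration:
  lambda_e_per_d: 2600.0          # RT-air/environment exchange, sitting awake
  rmv_icrp_female_l_per_h: 390.0
  rmv_icrp_male_l_per_h: 540.0
  v_rt_female_l: 3.131
  v_rt_male_l: 3.858
tissues:
  - {name: fat_1,      flow_fraction: 0.033, partition: 11.0, volume_l: 9.35}
  - {name: bone_1,     flow_fraction: 0.010, partition: 0.41, volume_l: 1.00}
  - {name: bone_2,     flow_fraction: 0.005, partition: 0.41, volume_l: 2.30}
  - {name: breast_g,   flow_fraction: 0.002, partition: 0.70, volume_l: 0.25}
  - {name: breast_a,   flow_fraction: 0.003, partition: 11.0, volume_l: 0.25}
  - {name: kidneys,    flow_fraction: 0.170, partition: 0.66, volume_l: 0.275}
  - {name: liver,      flow_fraction: 0.250, partition: 0.71, volume_l: 1.40}
  - {name: red_marrow, flow_fraction: 0.030, partition: 5.00, volume_l: 0.90}
  - {name: remaining,  flow_fraction: 0.430, partition: 0.70, volume_l: 30.0}
provenance:
  physical.lambda_r_per_h: paper
  blood.cardiac_output_l_per_h: reference-config
  blood.v_arterial_l: reference-config
  blood.v_venous_l: reference-config
  blood.p_blood_air: reference-config
  skin.k0_m_per_s: paper
  skin.p_sw: paper
  skin.p_sa: assumption
  skin.p_dsb: paper
  skin.p_ssb: paper
  skin.v_ds_l: paper
  skin.v_ss_l: paper
  skin.area_m2: paper
  skin.exposed_fraction: paper
  skin.k_ds_per_h: paper
  skin.flow_fraction_ds: paper
  skin.flow_fraction_ss: paper
  skin.kappa_dry: assumption
  modulation.ramp_factor: paper
  modulation.ramp_end_min: paper
  modulation.swell_start_min: paper
  modulation.swell_factor: paper
  modulation.swell_end_min: paper
  modulation.kds_coupling: paper
  modulation.apply_swelling: paper
  instrument.v_dead_l: paper
  instrument.sampling_interval_min: paper
  respiration.lambda_e_per_d: paper
  respiration.rmv_icrp_female_l_per_h: paper
  respiration.rmv_icrp_male_l_per_h: paper
  respiration.v_rt_female_l: paper
  respiration.v_rt_male_l: paper
  tissues: reference-config
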