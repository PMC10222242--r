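drug:
  name: bempedoic acid
  molecular_weight: 344.5
  log_p: 4.328
  pka1: 4.88
  pka2: 5.6
  intrinsic_solubility_mg_ml: 0.0051
  particle_density_g_cm3: 1.2
permeability:
  caco2_1e6_cm_s: 11.5
  peff_cm_s: 0.0003
dose_mg: 180.0
formulations:
  tablet:
    form: tablet
    dose_mg: 180.0
    median_particle_diameter_d50_um: 36.4
    fraction_dose_dissolved_initial: 0.0
    dlm_scalar: 0.07
  suspension:
    form: suspension
    dose_mg: 180.0
    median_particle_diameter_d50_um: 50.0
    fraction_dose_dissolved_initial: 0.0001
    vehicle_concentration_mg_ml: 20.0
    vehicle_viscosity_cps: 118.8
    dlm_scalar: 0.3
  solution:
    form: solution
    dose_mg: 240.0
    fraction_dose_dissolved_initial: 1.0
    dlm_scalar: 1.0
disposition:
  cl_oral_l_h: 0.81
  cl_renal_l_h: 0.03
  blood_plasma_ratio: 0.55
  fu_plasma: 0.026
  fa: 0.97
  fg: 1.0
  uptake: 1.0
  q_h_l_h: 90.0
  kp_scalar: 2.0
  vss_l_kg: 0.14
  v_sac_l_kg: 0.1
  cl_in_l_h: 3.16
  cl_out_l_h: 1.32
physiology:
  gastric_mrt_h: 0.4
  si_transit_h: 3.34
  colon_mrt_h: 12.0
  stomach_ph: 1.5
population:
  n_subjects: 59.0
  age_min: 20.0
  age_max: 60.0
  proportion_female: 0.5
  occasion_cv: 0.05
  variability:
    cl_u_int: 0.35
    fu_plasma: 0.1
    gastric_mrt: 0.38
    si_transit: 0.25
    colon_mrt: 0.3
    liver_mass: 0.2
    q_h: 0.2
    weight: 0.15
    height: 0.04
    stomach_ph_sd: 0.3
trial:
  schedule_study: '004'
  washout_days: 14.0
  n_trials: 10.0
seed: 1
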