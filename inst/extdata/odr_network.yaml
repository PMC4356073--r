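# Network configuration: four two-layer PFC columns with D1/D2 modulation
# and the ODR task protocol.
#
# Population counts and connection probabilities follow the reference
# circuit (counts at scale 1; the default inter-group probability is 0.1;
# the within-column probability set is a repo default). Synaptic weight
# values are not fixed by the reference; the values below are the output of
# the staged calibration (calibrate_bistability) at the desk scale 0.1,
# stored at scale 1 (the builder multiplies by 1/scale).
scale: 0.1
seed: 42
use_140_constant: true
populations:
  L3_exc: 2585
  L3_inh: 729
  L5_exc: 606
  L5_inh: 133
  MDSC: 1000
  VTA: 1000
  BG_relay: 500
  BG_tonic: 500
  INH_pool: 1000
  THAL: 1000
  MOT: 1000
  MOT_inh: 400
  PC: 1000
  MDSC_gen: 1000
  PACE_gen: 500
  THAL_gen: 1000
probabilities:
  ee: 0.12
  ei: 0.15
  ie: 0.2
  ii: 0.1
  default: 0.1
weights:
  pc_l3: 0.004
  l3_ee: 0.0027
  l3_ei: 0.0006
  l3_ie: 0.0012
  l3_ii: 0.0002
  l5_ee: 0.002
  l5_ei: 0.001
  l5_ie: 0.0004
  l5_ii: 0.0002
  l3_lat_ee: 0.00095
  l3_lat_ei: 0.0055
  l3_mot: 0.0046
  mot_moti: 0.001
  moti_mot: 0.0005
  mdscgen_mdsc: 0.005
  mdsc_l5: 0.003
  l5_inhpool: 0.002
  inhpool_l3: 0.0024
  l5_bgrelay: 0.002
  bgrelay_bgtonic: 0.004
  pace_bgtonic: 0.02
  bgtonic_thal: 0.006
  thalgen_thal: 0.006
  thal_l3: 0.01
rates:
  pc_baseline: 5
  pc_cue: 35
  mdsc_baseline: 3
  mdsc_cd: 35
  pace: 8
  thal_drive: 25
timings:
  fixation_end: 1000
  cue_end: 1500
  delay_end: 4000
  trial_end: 6000
  cd_onset: 4000
  cd_duration: 500
  decision_window: 500
  decision_threshold: 6
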