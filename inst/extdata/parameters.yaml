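# CFM-Phyto-T cellular parameter profiles.
#
# All model constants live here, not in code, so alternative calibrations can
# be swapped without touching the implementation.  Units:
#   Pmax_ref  d-1    max chlorophyll-carbon-specific C fixation rate
#   a_I       (umol photons m-2 s-1)-1   light saturation coefficient
#   E_bio     -      carbon overhead (excretion) per unit growth
#   Rm_ref    d-1    maintenance carbohydrate consumption at T_ref
#   Q10_R     -      temperature sensitivity of maintenance respiration
#   k_bio_ref d-1    biosynthetic capacity at T_ref
#   Ea_bio    J mol-1  activation energy of biosynthesis
#   T_ref     K      reference temperature
#   f_pp      -      photosynthetic-protein C per unit chlorophyll C
#   f_thy     -      thylakoid-membrane C per unit chlorophyll C
#   C_ess     -      essential-pool C fraction of total cell C
#   N_store   mol N (mol C)-1   N-storage per unit total cell C
#   f_rna     -      RNA share of biosynthetic-pool carbon
#   f_dna_ess -      DNA share of essential-pool carbon
# comp: per-biomolecule N:C and P:C (mol mol-1).

default: &default
  Pmax_ref: 25.0
  a_I: 0.01
  E_bio: 0.25
  Rm_ref: 0.1
  Q10_R: 2.0
  k_bio_ref: 2.0
  Ea_bio: 70000.0
  T_ref: 293.15
  f_pp: 1.5
  f_thy: 0.4
  C_ess: 0.15
  N_store: 0.01
  f_rna: 0.35
  f_dna_ess: 0.1
  comp:
    protein:     {NC: 0.27,   PC: 0.0}
    rna:         {NC: 0.38,   PC: 0.105}
    dna:         {NC: 0.39,   PC: 0.105}
    chlorophyll: {NC: 0.0727, PC: 0.0}
    thylakoid:   {NC: 0.0,    PC: 0.024}
    carb_store:  {NC: 0.0,    PC: 0.0}
    n_store:     {NC: 0.5,    PC: 0.0}

profiles:
  # Average-community calibration (original CFM-Phyto constants).
  community:
    <<: *default
  # Eukaryote (Raphidocelis-like) calibration: raised maintenance carbohydrate
  # consumption and a larger essential pool.  Provisional deltas.
  eukaryote:
    <<: *default
    Rm_ref: 0.25
    C_ess: 0.18
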