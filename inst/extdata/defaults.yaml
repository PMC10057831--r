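# thrombosim default scenario configuration (schema_version 1)
#
# Internal unit system: concentrations in uM, time in s, space/pressure in SI
# (m, Pa). The only exception is drug C0, stored in nM as printed on drug
# labels/assay reports, converted to uM at load.
#
# Sections `drugs`, `patient` and the regimen definitions carry published,
# drug-specific constants. Sections `proteins`, `plasma_kinetics`, `clot` and
# `binding` are the CALIBRATION SURFACE: physiological constants for the
# plasma fibrinolytic system and the clot micro-structure that are not
# drug-specific. They ship with defaults drawn from the physiological
# literature on fibrinolysis modelling and may be tuned here (and only here)
# to match observed lysis behaviour; the model equations never change.
schema_version: 1

patient:
  body_weight: 80.0          # kg

drugs:
  alteplase:
    C0_nM: 0.05              # endogenous tPA baseline
    KM_plasma: 28.0          # uM, plasma-phase PLG activation
    kcat_plasma: 0.3         # 1/s
    kPAI: 37.0               # 1/(uM s), PAI-1 second-order inhibition
    kel: 2.27e-3             # 1/s
    kcp: 3.1e-4              # 1/s
    kpc: 3.34e-4             # 1/s
    Vc_per_kg: 0.057         # L/kg
    Mw: 59050.0              # g/mol
    ka: 0.01                 # 1/(uM s), fibrin adsorption
    kd_off: 0.0058           # 1/s, fibrin desorption (Kd = 0.58 uM)
    KM_clot: 0.16            # uM
    kcat_clot: 0.3           # 1/s
    fibrin_binding: true
    endogenous_secretion: true
  tenecteplase:
    C0_nM: 0.0
    KM_plasma: 20.0
    kcat_plasma: 0.04
    kPAI: 0.15
    kel: 3.89e-4
    kcp: 1.1e-4
    kpc: 1.37e-4
    Vc_per_kg: 0.0496
    Mw: 58500.0
    ka: 0.01
    kd_off: 0.0015           # Kd = 0.15 uM
    KM_clot: 2.8
    kcat_clot: 0.54
    fibrin_binding: true
    endogenous_secretion: false
  reteplase:
    C0_nM: 0.0
    KM_plasma: 0.2
    kcat_plasma: 3.3e-4
    kPAI: 37.0
    kel: 8.33e-4
    kcp: 1.82e-4
    kpc: 1.53e-4
    Vc_per_kg: 0.25
    Mw: 39571.0              # non-glycosylated deletion variant
    ka: 0.01
    kd_off: 0.011            # Kd = 1.1 uM
    KM_clot: 4.6
    kcat_clot: 0.32
    fibrin_binding: true
    endogenous_secretion: false
  urokinase:
    C0_nM: 0.7               # endogenous uPA baseline
    KM_plasma: 50.0
    kcat_plasma: 1.0
    kPAI: 160.0
    kel: 4.06e-4
    kcp: 4.39e-4
    kpc: 1.28e-4
    Vc_per_kg: 0.13
    Mw: 33000.0              # low-molecular-weight two-chain uPA
    ka: 0.0                  # no fibrin affinity
    kd_off: 0.0
    KM_clot: 0.81
    kcat_clot: 2.6
    fibrin_binding: false
    endogenous_secretion: true

# ---- calibration surface ----------------------------------------------

proteins:                    # C_init in uM, kel_i in 1/s
  PLG: {C_init: 2.2,    kel_i: 1.0e-4}   # effective turnover during lysis
  PLS: {C_init: 0.0,    kel_i: 1.0e-4}
  AP:  {C_init: 1.0,    kel_i: 5.0e-6}
  MG:  {C_init: 3.0,    kel_i: 5.0e-6}
  FBG: {C_init: 9.0,    kel_i: 2.6e-6}
  PAI: {C_init: 4.0e-4, kel_i: 2.8e-4}

plasma_kinetics:             # second-order mass action, 1/(uM s)
  k_AP: 10.0                 # PLS + alpha2-antiplasmin
  k_MG: 0.05                 # PLS + alpha2-macroglobulin
  k_FBG: 0.06                # PLS-mediated fibrinogen degradation

clot:
  L_clot: 0.015              # m, long MCA occlusion along flow
  epsilon_clot: 0.6          # initial porosity (compacted, platelet-rich)
  fiber_radius: 1.0e-6       # m, coarse fibrin bundles
  n_total_init: 8.0          # uM, fibrin binding sites
  dp_per_length: 2.9e+5      # Pa/m, pressure gradient across occlusion
  pressure_mode: gradient    # gradient | total (fixed total drop over L_clot)
  mu: 1.5e-3                 # Pa s, plasma viscosity
  U_max: 5.0e-4              # m/s, downstream-resistance velocity limit
  D_i: 1.0e-11               # m^2/s, in-clot protein diffusivity
  kdeg: 0.03                 # 1/s, lysis coefficient
  gamma: 10.0                # plasmin cuts per fibrin unit
  x_monitor: 0.005           # m, activation-time monitoring position
  PAI_clot_init: 0.01        # uM, matrix-bound platelet PAI-1 stock (immobile)
  entry_length: 0.0          # m, clot-free entry region (porosity 1)

binding:                     # clot-phase adsorption of PLG and PLS
  ka_PLG: 0.01               # 1/(uM s)
  kd_PLG: 1.1                # 1/s (Kd 110 uM: Glu-PLG on intact fibrin)
  ka_PLS: 0.01
  kd_PLS: 0.0075             # 1/s: plasmin held tightly at lysine sites
  init_bound_equilibrium: true
  bound_PLS_protected: true  # AP/MG act on free plasmin only

metrics:
  lysis_threshold: 0.05      # fraction of initial sites counted as lysed
  activation_drop: 0.10      # fractional site loss that marks activation

solver:
  n_cells: 50
  dt: 0.5                    # s, outer transport/reaction step
  output_dt: 15.0            # s, space-time recording cadence
  sub_rate_target: 0.2       # max fractional change per reaction sub-step
  rtol: 1.0e-8               # systemic integrator
  atol: 1.0e-12
  dt_out_systemic: 5.0       # s
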