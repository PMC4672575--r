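# Default parameter catalogue for the bystander-effect cellular automaton.
# Every entry is addressable as catalogue$<section>$... after
# `default_catalogue()`; distributions are truncated normals described by
# av (mean), sd (standard deviation) and min (lower truncation bound,
# exclusive). Phase-dependent entries name a group per cell-cycle phase and
# one distribution per group.
time:
  dt_s: 0.1
lattice:
  grid_spacing_m: 1.0e-05
irradiation:
  d1track_gy: 1.0e-03          # dose per track traversal (60Co gamma)
  tracks_per_min: 1000         # mean track arrivals per grid per minute
signal:
  mdp:                         # medium-mediated pathway
    w_m2_s: 1.0e-10            # diffusion constant
    alpha_unit_gy: 1.0         # signal production per Gy
    beta_s: 4.6e-06            # first-order decay constant
  gjp:                         # gap-junctional pathway
    w_m2_s: 5.0e-11
    alpha_unit_gy: 1.0
    beta_s: 1.18e-03
cell:
  zr_lambda:                   # DSB induction per Gy of direct dose
    units: DSBs/Gy
    groups: {G0: g0g1, G1: g0g1, S: s, G2: g2, M1: m, M2: m}
    values:
      g0g1: {av: 40.0, sd: 22.0, min: 0.0}
      s:    {av: 80.0, sd: 24.0, min: 0.0}
      g2:   {av: 80.0, sd: 26.0, min: 0.0}
      m:    {av: 80.0, sd: 16.0, min: 0.0}
  zm_lambda:                   # DSB induction per unit MDP signal per second
    units: DSBs/unit/s
    groups: {G0: g0g1, G1: g0g1, S: sg2m, G2: sg2m, M1: sg2m, M2: sg2m}
    values:
      g0g1: {av: 6.0e-03, sd: 1.0e-02, min: 0.0}
      sg2m: {av: 1.2e-02, sd: 1.0e-02, min: 0.0}
  zg_lambda:                   # DSB induction per unit GJP signal per second
    units: DSBs/unit/s
    groups: {G0: g0g1, G1: g0g1, S: sg2m, G2: sg2m, M1: sg2m, M2: sg2m}
    values:
      g0g1: {av: 6.0e-02, sd: 1.0e-02, min: 0.0}
      sg2m: {av: 1.2e-01, sd: 1.0e-02, min: 0.0}
  zb_lambda:                   # endogenous background DSB induction
    units: DSBs/s
    groups: {G0: g0g1, G1: g0g1, S: sg2m, G2: sg2m, M1: sg2m, M2: sg2m}
    values:
      g0g1: {av: 1.4e-05, sd: 0.0, min: 0.0}
      sg2m: {av: 2.8e-05, sd: 0.0, min: 0.0}
  repair_lambda:               # per-DSB repair probability (per step)
    units: 1/s
    groups: {G0: g0g1, G1: g0g1, S: sg2m, G2: sg2m, M1: sg2m, M2: sg2m}
    values:
      g0g1: {av: 9.33e-07, sd: 2.0e-05, min: 0.0}
      sg2m: {av: 7.45e-07, sd: 2.0e-05, min: 0.0}
  prd_threshold:               # DSBs triggering PR -> pre-reproductive-death
    units: DSBs
    groups: {G0: g0g1, G1: g0g1, S: s, G2: g2, M1: m, M2: m}
    values:
      g0g1: {av: 93.0,  sd: 38.0,  min: 0.0}
      s:    {av: 42.0,  sd: 144.0, min: 0.0}
      g2:   {av: 116.0, sd: 124.0, min: 0.0}
      m:    {av: 22.0,  sd: 91.0,  min: 0.0}
  pid_threshold:               # DSBs triggering PR -> pre-interphase-death
    units: DSBs
    groups: {G0: g0g1, G1: g0g1, S: s, G2: g2, M1: m, M2: m}
    values:
      g0g1: {av: 186.0, sd: 38.0,  min: 0.0}
      s:    {av: 84.0,  sd: 144.0, min: 0.0}
      g2:   {av: 232.0, sd: 124.0, min: 0.0}
      m:    {av: 44.0,  sd: 91.0,  min: 0.0}
checkpoint:
  arrest_threshold:            # DSBs at or above which the clock halts
    units: DSBs
    values:
      g1s:  {av: 5.0,  sd: 1.0, min: 0.0}
      sg2:  {av: 40.0, sd: 8.0, min: 0.0}
      g2m1: {av: 20.0, sd: 4.0, min: 0.0}
      m1m2: {av: 40.0, sd: 8.0, min: 0.0}
period:                        # cell-cycle phase durations
  units: h
  values:
    G1: {av: 11.0, sd: 2.2, min: 0.0}
    S:  {av: 8.0,  sd: 1.6, min: 0.0}
    G2: {av: 4.0,  sd: 0.8, min: 0.0}
    M1: {av: 0.5,  sd: 0.1, min: 0.0}
    M2: {av: 0.5,  sd: 0.1, min: 0.0}
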