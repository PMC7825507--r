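# Example rhizosim configuration: Mer Bleue-style soil profile, default
# root segment, built-in solute table, reference numerics.
soil:
  a_rho: 0.0107
  b_rho: 0.567
  gs: 1.5
  m: 2.3
  i_mb: 0.0287
  j_mb: -0.024
  x_T: 17.8
  y_T: 2.12
  q10: 2.3
root:
  r0_cm: 0.0641885
  Em_mV: -120
  v0_cm3_s: 0
solutes: solutes.csv
numerics:
  n_annuli: 500
  dr_cm: 0.02
  dt_s: 1
  eq_rel_tol: 1.0e-7
  threshold_nmol: 0.01
outputs:
  dir: rhizosim-output
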