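# Generic cell / physiological medium configuration (schema version 1).
# All physics defaults of the energy engine are surfaced here.
schema_version: 1
cell:
  name: generic cell
  gamma_lw: 39        # mJ/m^2
  gamma_plus: 2.6     # mJ/m^2
  gamma_minus: 71     # mJ/m^2
  psi0_mv: -40        # surface potential, mV
medium:
  name: water
  gamma_lw: 21.8
  gamma_plus: 25.5
  gamma_minus: 25.5
  relative_permittivity: 74
  debye_length_nm: 0.78   # physiological 0.154 M 1:1 electrolyte at 310 K
  temperature_k: 310
xdlvo:
  d0_nm: 0.157        # minimum contact separation
  lambda_ab_nm: 0.6   # acid-base decay length in water
  d_max_nm: 20
  n_grid: 2000
vesicle_rule:
  offset_nm: 0        # vesicle radius = NP radius + offset
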