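# Reference run configuration: all supported keys with their defaults.
# Unknown keys are rejected; omitted keys take the values below.
kinetics:
  alpha: 1.0        # reaction-rate prefactor (diffusion time / reaction time)
  kappa1: 0.2       # NMIIA half-saturation in RhoA recruitment
  kappa2: 0.2       # RhoA half-saturation in NMIIA recruitment
  "n": 4            # Hill coefficient (quoted: bare n is a YAML boolean)
mechanics:
  pe: 12.0          # Peclet number (advection / diffusion)
  K: 1.0            # active-stress half-saturation
  advection_mode: both   # both | myosin_only
grid:
  length: 40.0      # domain size (screening-length units)
  n_cells: 400
  bc: noflux_rigid  # noflux_rigid | periodic
init:
  amplitude: ~      # ~ means: use the high-state concentration
  half_width: 1.0
  species: rho      # rho | both
  shape: tophat     # tophat | gaussian
# protocol:         # optional perturbation block, e.g. the inhibition run
#   t_switch: 40
#   pe_after: 0
#   nmiia_decay_factor: 2
#   rho_decay_factor: 2
t_end: 200.0
record_every: 1.0
scheme: muscl       # muscl | upwind
seed: 1             # used only by the synthetic-kymograph generator
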