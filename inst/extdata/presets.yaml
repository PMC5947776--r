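# Named toy-crystal scenarios: cell edge (A, cubic P1), atom count,
# resolution d_min (A), amplitude noise fraction, free-set fraction,
# per-atom U range (A^2), and the perturbation defining the start model.
small_clean:
  cell: 18
  n_atoms: 12
  d_min: 2.0
  noise_frac: 0.0
  free_fraction: 0.05
  u_min: 0.1
  u_max: 0.4
  arrangement: random
  perturb: reset_u
  magnitude: 0.5
small_noisy:
  cell: 18
  n_atoms: 12
  d_min: 2.0
  noise_frac: 0.05
  free_fraction: 0.05
  u_min: 0.1
  u_max: 0.4
  arrangement: random
  perturb: reset_u
  magnitude: 0.5
medium_2A:
  cell: 30
  n_atoms: 50
  d_min: 2.0
  noise_frac: 0.02
  free_fraction: 0.05
  u_min: 0.1
  u_max: 0.4
  arrangement: random
  perturb: reset_u
  magnitude: 0.5
hires_1.5A:
  cell: 22
  n_atoms: 20
  d_min: 1.5
  noise_frac: 0.02
  free_fraction: 0.05
  u_min: 0.08
  u_max: 0.35
  arrangement: random
  perturb: reset_u
  magnitude: 0.5
lowres_3.5A:
  cell: 22
  n_atoms: 20
  d_min: 3.5
  noise_frac: 0.02
  free_fraction: 0.05
  u_min: 0.08
  u_max: 0.35
  arrangement: random
  perturb: reset_u
  magnitude: 0.5
two_domain_shift:
  cell: 30
  n_atoms: 40
  d_min: 2.5
  noise_frac: 0.02
  free_fraction: 0.05
  u_min: 0.1
  u_max: 0.3
  arrangement: two_domain
  perturb: rigid_shift_domain
  magnitude: 0.8
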