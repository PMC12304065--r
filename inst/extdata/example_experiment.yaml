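# Hill-growth / tanh-drift example: reference PDE solve plus N = M = 2
# Gaussian-closure reduction, with a comparison report.
model:
  type: hill_tanh
  params:
    f_max: 2
    k_x: 0.4
    V_max: 0.5
    omega: 1
domain: [0.0, 1.2]
beta: 1.0e-4
kappa: 0.1
initial:
  x_bar0: 0.2
  sigma0: 0.02
  P0: 1
pde:
  nx: 600
  t_end: 35
  n_out: 141
reduction:
  N: 2
  M: 2
  closure: gaussian
run: [pde, reduction]
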