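# Simulation config for the densely methylated Xi-linked regime
# (FMR1-like): strongly processive DNMT1, near-perfect maintenance,
# nearly inactive DNMT3s, 2% inappropriate-conversion error.
n_patterns: 169
n_sites: 22
seed: 1
variant: in_vivo_default
r1: 0.12
d1: 0.002
r3p: 0.01
d3p: 0.65
r3d: 0.01
d3d: 0.28
mu1: 0.99
delta1: 0.02
mu3: 1.0
delta3: 1.0
e_fail: 0.003
e_inap: 0.02
densities: 0.88
crossover_rate: 0.0
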