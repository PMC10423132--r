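# Fish (species 1) coupled to a logistically growing fishermen
# population (species 2) in amensalism: the fishermen grow
# independently (alpha2 = 0) and inhibit the fish through the
# manipulated coupling alpha1.  r2 is calibrated so the fishermen reach
# 99% of N2 in 60 months (transitory-time inversion: ln(891)/60).
# Fishing seasons regulate the fish to 45% of N1, growing seasons to
# 65% of N1.
name: coexist_amensalism
model: coexist
params:
  r1: 0.8
  r2: 0.1132057404578468   # /month, ln(891)/60
  N1: 780500               # fish
  N2: 5000                 # fishermen
  alpha1: -156.1           # nominal -N1/N2; overridden in closed loop
  alpha2: 0
  x01: 10000
  x02: 500
step: 0.01
control:
  K: 1
controlled_species: 1
seasons:
  - {duration: 12, mode: decoupled}
  - {duration: 6, mode: closed_loop, reference_fraction: 0.45}
  - {duration: 6, mode: closed_loop, reference_fraction: 0.65}
  - {duration: 6, mode: closed_loop, reference_fraction: 0.45}
  - {duration: 6, mode: closed_loop, reference_fraction: 0.65}
  - {duration: 6, mode: closed_loop, reference_fraction: 0.45}
  - {duration: 6, mode: closed_loop, reference_fraction: 0.65}
  - {duration: 6, mode: closed_loop, reference_fraction: 0.45}
  - {duration: 6, mode: closed_loop, reference_fraction: 0.65}
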