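# Fish population harvested by a crew of v fishermen, regulated by the
# coupling-parameter control law: 12 months of free growth, then
# alternating 6-month fishing (reference 65% of N) and growing
# (reference 90% of N) seasons up to 60 months.
# alpha is the nominal maximum per-fisherman capacity -N/1000; it is
# overridden each step in closed-loop seasons.
name: coupled_fish_closed_loop
model: coupled
params:
  r: 0.8          # /month
  "N": 780500       # fish
  alpha: -780.5   # fish per fisherman (nominal -N/1000)
  x0: 10000       # fish
v_level: 1000     # fishermen
step: 0.01
control:
  K: 1
seasons:
  - {duration: 12, mode: decoupled}
  - {duration: 6, mode: closed_loop, reference_fraction: 0.65}
  - {duration: 6, mode: closed_loop, reference_fraction: 0.90}
  - {duration: 6, mode: closed_loop, reference_fraction: 0.65}
  - {duration: 6, mode: closed_loop, reference_fraction: 0.90}
  - {duration: 6, mode: closed_loop, reference_fraction: 0.65}
  - {duration: 6, mode: closed_loop, reference_fraction: 0.90}
  - {duration: 6, mode: closed_loop, reference_fraction: 0.65}
  - {duration: 6, mode: closed_loop, reference_fraction: 0.90}
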