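# Maximum-capacity harvesting study: after 12 months of free growth the
# coupling is held at the nominal capacity alpha0 = -N/1000 for the
# remaining 48 months.  With v_level = 1000 the stock survives; raising
# v_level to 2000 or 3000 drives it extinct.
name: coupled_fish_open_loop
model: coupled
params:
  r: 0.8
  "N": 780500
  alpha: -780.5   # alpha0 = -N/1000
  x0: 10000
v_level: 1000
step: 0.01
seasons:
  - {duration: 12, mode: decoupled}
  - {duration: 48, mode: open_loop, alpha: -780.5}
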