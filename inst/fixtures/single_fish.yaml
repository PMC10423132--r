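# Uncoupled fish population growing freely for 12 months.
# Units: times in months, populations in individuals.
name: single_fish
model: single
params:
  r: 0.8        # /month
  "N": 780500     # fish
  x0: 6000      # fish (the study also uses 800 and 1000)
step: 0.01
seasons:
  - {duration: 12, mode: decoupled}
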