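# Stand-alone complete TCA cycle operating on malate, scaled to deliver
# 8 NADH (all bifurcated) per N2: 1.6 malate fully oxidised to CO2.
# NADH:QH2 = 5:1.
name: TCA-malate
substrate_label: 1.6Mal
product_label: CO2
substrates:
  malate: 1.6
products:
  co2: 6.4
reaction_steps: 11
nadh_total: 8
nadh_bifurcated: 8
qh2_catabolic: 1.6
extra_electrons_to_oxidase: 0
h_enzymatic_consumed: 5.2
substrate_level_atp: 1.6
n_atoms:
  malate: 0
non_reconciled: false
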