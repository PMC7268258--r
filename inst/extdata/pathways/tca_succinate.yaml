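# Stand-alone complete TCA cycle operating on succinate, scaled to deliver
# 8 NADH per N2: 1.6 succinate fully oxidised to CO2. NADH:QH2 = 5:2.
# non_reconciled: the reported translocation term (43.6 H+) exceeds the
# 43.2 H+ implied by 8 NADH + 3.2 QH2 (14.4 oxidase electrons), and the
# reported net ATP (0.12) is not recovered by the accounting identity
# (which yields 0.24). The fixture carries the bracket-derived electron
# flux (43.6/3) as authoritative; exact accounting checks exclude it.
name: TCA-succinate
substrate_label: 1.6Suc
product_label: CO2
substrates:
  succinate: 1.6
products:
  co2: 6.4
reaction_steps: 11
nadh_total: 8
nadh_bifurcated: 8
qh2_catabolic: 3.2
extra_electrons_to_oxidase: 0.13333333333333333
h_enzymatic_consumed: 5.2
substrate_level_atp: 1.6
n_atoms:
  succinate: 0
non_reconciled: true
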