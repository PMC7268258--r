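# CATCH-N cycle, succinate co-substrate, aspartate-secreting variant
# (transamination onto oxaloacetate). Lower enzymatic proton consumption
# than the alanine variant. Stoichiometry per N2 reduced.
name: CATCH-N2
substrate_label: 2Suc, 2Arg
product_label: 2Asp
substrates:
  succinate: 2
  arginine: 2
products:
  aspartate: 2
reaction_steps: 9
nadh_total: 8
nadh_bifurcated: 8
qh2_catabolic: 4
extra_electrons_to_oxidase: 0
h_enzymatic_consumed: 4
substrate_level_atp: 2
amino_acid_product: aspartate
transaminations_per_arginine: 2
n_atoms:
  arginine: 4
  succinate: 0
  aspartate: 1
non_reconciled: false
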