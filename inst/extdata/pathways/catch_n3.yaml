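# CATCH-N cycle, malate co-substrate, alanine-secreting variant.
# The malate variants list 1 net catabolic QH2; the oxidase electron flux
# implied by their proton-translocation term (36 H+ = 12 electrons) exceeds
# bifurcated NADH + 2*QH2 by 2, carried here as extra_electrons_to_oxidase
# (quinone-pool feed at another network node).
name: CATCH-N3
substrate_label: 2Mal, 2Arg
product_label: 2Ala
substrates:
  malate: 2
  arginine: 2
products:
  alanine: 2
reaction_steps: 9
nadh_total: 8
nadh_bifurcated: 8
qh2_catabolic: 1
extra_electrons_to_oxidase: 2
h_enzymatic_consumed: 8
substrate_level_atp: 2
amino_acid_product: alanine
transaminations_per_arginine: 2
n_atoms:
  arginine: 4
  malate: 0
  alanine: 1
non_reconciled: false
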