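# CATCH-N cycle, succinate co-substrate, alanine-secreting variant.
# Stoichiometry is per N2 reduced (two cycle turns, 2 arginine).
# substrate_level_atp is not independently measurable from the flux table;
# it is the enzyme-coupled ATP of the cycle back-solved from the net-ATP
# accounting identity on this and the aspartate variant (synthetic fixture
# value, see package vignette).
name: CATCH-N1
substrate_label: 2Suc, 2Arg
product_label: 2Ala
substrates:
  succinate: 2
  arginine: 2
products:
  alanine: 2
reaction_steps: 9
nadh_total: 8
nadh_bifurcated: 8
qh2_catabolic: 4
extra_electrons_to_oxidase: 0
h_enzymatic_consumed: 8
substrate_level_atp: 2
amino_acid_product: alanine
transaminations_per_arginine: 2
n_atoms:
  arginine: 4
  succinate: 0
  alanine: 1
non_reconciled: false
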