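# Arginine transamination reaction network: arginine to succinate through
# guanidino/amino C5-C4 intermediates, with pyruvate as the amino acceptor.
# carbon/nitrogen are whole-molecule atom counts used for balance checks.
# Rates are order-of-magnitude defaults (min^-1; aminotransferases
# mM^-1 min^-1, second order in the pyruvate acceptor); no kinetic
# constants are fitted.
metabolites:
  - {id: ARG,  name: arginine,                     carbon: 6, nitrogen: 4, guanidino: true}
  - {id: ORN,  name: ornithine,                    carbon: 5, nitrogen: 2, guanidino: false}
  - {id: GOP,  name: 5-guanidino-2-oxopentanoate,  carbon: 6, nitrogen: 3, guanidino: true}
  - {id: AGM,  name: agmatine,                     carbon: 5, nitrogen: 4, guanidino: true}
  - {id: AOP,  name: 5-amino-oxopentanoate,        carbon: 5, nitrogen: 1, guanidino: false}
  - {id: PUT,  name: putrescine,                   carbon: 4, nitrogen: 2, guanidino: false}
  - {id: GBL,  name: 4-guanidinobutyraldehyde,     carbon: 5, nitrogen: 3, guanidino: true}
  - {id: ABL,  name: 4-aminobutyraldehyde,         carbon: 4, nitrogen: 1, guanidino: false}
  - {id: GBA,  name: 4-guanidinobutanoate,         carbon: 5, nitrogen: 3, guanidino: true}
  - {id: GABA, name: 4-aminobutanoate,             carbon: 4, nitrogen: 1, guanidino: false}
  - {id: SSA,  name: succinic semialdehyde,        carbon: 4, nitrogen: 0, guanidino: false}
  - {id: SUCC, name: succinate,                    carbon: 4, nitrogen: 0, guanidino: false}
  - {id: CIT,  name: citrulline,                   carbon: 6, nitrogen: 3, guanidino: false, optional: true}
  - {id: PRO,  name: proline,                      carbon: 5, nitrogen: 1, guanidino: false, optional: true}
  - {id: GLU,  name: glutamate,                    carbon: 5, nitrogen: 1, guanidino: false, optional: true}
  - {id: PYR,  name: pyruvate,                     carbon: 3, nitrogen: 0, guanidino: false}
  - {id: ALA,  name: alanine,                      carbon: 3, nitrogen: 1, guanidino: false}
  - {id: ASP,  name: aspartate,                    carbon: 4, nitrogen: 1, guanidino: false, optional: true}
  - {id: UREA, name: urea,                         carbon: 1, nitrogen: 2, guanidino: false}
  - {id: NH4,  name: ammonium,                     carbon: 0, nitrogen: 1, guanidino: false}
  - {id: CO2,  name: carbon dioxide,               carbon: 1, nitrogen: 0, guanidino: false}
  - {id: NADH, name: NADH (produced; NAD+ pool non-limiting), carbon: 0, nitrogen: 0, guanidino: false}
edges:
  - {substrate: ARG,  product: ORN,  class: ureohydrolase,    enzymes: [ArgI1],               rate: 0.03}
  - {substrate: ARG,  product: GOP,  class: aminotransferase, enzymes: [AspC],                rate: 0.002}
  - {substrate: ARG,  product: AGM,  class: decarboxylase,    enzymes: [arginine decarboxylase], rate: 0.01}
  - {substrate: ARG,  product: CIT,  class: deiminase,        enzymes: [ArcA1, ArcA2],        rate: 0.01, optional: true}
  - {substrate: ORN,  product: AOP,  class: aminotransferase, enzymes: [DatA],                rate: 0.005}
  - {substrate: ORN,  product: PUT,  class: decarboxylase,    enzymes: [OdcA],                rate: 0.1}
  - {substrate: ORN,  product: PRO,  class: deiminase,        enzymes: [ornithine cyclodeaminase], rate: 0.01, optional: true}
  - {substrate: PRO,  product: GLU,  class: dehydrogenase,    enzymes: [proline dehydrogenase], rate: 0.01, optional: true}
  - {substrate: GOP,  product: GBL,  class: decarboxylase,    enzymes: [IlvB1],               rate: 0.1}
  - {substrate: GOP,  product: AOP,  class: ureohydrolase,    enzymes: [SpeB2],               rate: 0.05}
  - {substrate: AGM,  product: PUT,  class: ureohydrolase,    enzymes: [ArgI2, SpeB],         rate: 0.1}
  - {substrate: AGM,  product: GBL,  class: aminotransferase, enzymes: [AatB],                rate: 0.005}
  - {substrate: AOP,  product: ABL,  class: decarboxylase,    enzymes: [OdcB],                rate: 0.15}
  - {substrate: PUT,  product: ABL,  class: aminotransferase, enzymes: [AatB],                rate: 0.008}
  - {substrate: GBL,  product: GBA,  class: dehydrogenase,    enzymes: [GabD8, GabD9],        rate: 0.1}
  - {substrate: GBL,  product: ABL,  class: ureohydrolase,    enzymes: [SpeB2],               rate: 0.05}
  - {substrate: GBA,  product: GABA, class: ureohydrolase,    enzymes: [SpeB2],               rate: 0.15}
  - {substrate: ABL,  product: GABA, class: dehydrogenase,    enzymes: [GabD1, GabD6, GabD7], rate: 0.2}
  - {substrate: GABA, product: SSA,  class: aminotransferase, enzymes: [GabT2, GabT3],        rate: 0.01}
  - {substrate: SSA,  product: SUCC, class: dehydrogenase,    enzymes: [GabD1, GabD6, GabD7], rate: 0.3}
  - {substrate: UREA, product: NH4,  class: urease,           enzymes: [UreABC],              rate: 0.05, optional: true}
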