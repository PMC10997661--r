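# Functional-group vocabulary for the FunctionalGroup reduced graph.
# Matching is greedy and non-overlapping, largest pattern (atom count)
# first, ties broken by list order.
groups:
  - {name: anhydride,        smarts: "[CX3](=O)[OX2][CX3](=O)"}
  - {name: carbamate,        smarts: "[NX3][CX3](=O)[OX2H0]"}
  - {name: urea,             smarts: "[NX3][CX3](=O)[NX3]"}
  - {name: thiourea,         smarts: "[NX3][CX3](=S)[NX3]"}
  - {name: guanidine,        smarts: "[NX3][CX3](=[NX2])[NX3]"}
  - {name: sulfonamide,      smarts: "[SX4](=O)(=O)[NX3]"}
  - {name: sulfonic_acid,    smarts: "[SX4](=O)(=O)[OX2H]"}
  - {name: sulfonate_ester,  smarts: "[SX4](=O)(=O)[OX2H0]"}
  - {name: sulfone,          smarts: "[SX4](=O)(=O)([#6])[#6]"}
  - {name: phosphate,        smarts: "[PX4](=O)([OX2])([OX2])[OX2]"}
  - {name: phosphonate,      smarts: "[PX4](=O)([OX2])[#6]"}
  - {name: carboxylic_acid,  smarts: "[CX3](=O)[OX2H1]"}
  - {name: ester,            smarts: "[CX3](=O)[OX2H0][#6]"}
  - {name: amide,            smarts: "[CX3](=O)[NX3]"}
  - {name: acyl_halide,      smarts: "[CX3](=O)[F,Cl,Br,I]"}
  - {name: aldehyde,         smarts: "[CX3H1](=O)[#6]"}
  - {name: ketone,           smarts: "[#6][CX3](=O)[#6]"}
  - {name: oxime,            smarts: "[CX3]=[NX2][OX2H]"}
  - {name: imine,            smarts: "[CX3]=[NX2]"}
  - {name: nitro,            smarts: "[$([NX3](=O)=O),$([NX3+](=O)[O-])]"}
  - {name: nitroso,          smarts: "[NX2]=[OX1]"}
  - {name: nitrile,          smarts: "[NX1]#[CX2]"}
  - {name: azide,            smarts: "N=[N+]=[N-]"}
  - {name: azo,              smarts: "[#6][NX2]=[NX2][#6]"}
  - {name: isocyanate,       smarts: "[NX2]=[CX2]=[OX1]"}
  - {name: epoxide,          smarts: "[OX2r3]1[#6r3][#6r3]1"}
  - {name: disulfide,        smarts: "[SX2][SX2]"}
  - {name: thiol,            smarts: "[SX2H]"}
  - {name: thioether,        smarts: "[#6][SX2][#6]"}
  - {name: sulfoxide,        smarts: "[#16X3]=[OX1]"}
  - {name: phenol,           smarts: "[c][OX2H]"}
  - {name: hydroxyl,         smarts: "[OX2H]"}
  - {name: ether,            smarts: "[#6][OX2H0][#6]"}
  - {name: primary_amine,    smarts: "[NX3;H2;!$(NC=O)]"}
  - {name: secondary_amine,  smarts: "[NX3;H1;!$(NC=O)]([#6])[#6]"}
  - {name: tertiary_amine,   smarts: "[NX3;H0;+0;!$(NC=O);!$(N=O)]([#6])([#6])[#6]"}
  - {name: alkyne,           smarts: "[CX2]#[CX2]"}
  - {name: alkene,           smarts: "[CX3]=[CX3]"}
  - {name: fluoro,           smarts: "[F]"}
  - {name: chloro,           smarts: "[Cl]"}
  - {name: bromo,            smarts: "[Br]"}
  - {name: iodo,             smarts: "[I]"}
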