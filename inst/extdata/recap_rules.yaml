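# RECAP retrosynthetic bond-cleavage rules.
# `cut` gives the (1-based) positions, within each SMARTS match, of the two
# atoms whose connecting acyclic bond is cleaved.
rules:
  - {name: amide,            smarts: "[NX3]!@[CX3]=[OX1]",                  cut: [1, 2]}
  - {name: ester,            smarts: "[OX2]!@[CX3]=[OX1]",                  cut: [1, 2]}
  - {name: urea,             smarts: "[NX3][CX3](=[OX1])!@[NX3]",           cut: [2, 4]}
  - {name: amine,            smarts: "[NX3;!$(N[C,S]=[O,S,N])]!@[CX4]",     cut: [1, 2]}
  - {name: ether,            smarts: "[#6][OX2;!$(OC=[O,S,N])]!@[#6]",      cut: [2, 3]}
  - {name: olefin,           smarts: "[CX3]=!@[CX3]",                       cut: [1, 2]}
  - {name: quaternary_n,     smarts: "[NX4+]!@[#6]",                        cut: [1, 2]}
  - {name: aromatic_n_to_c,  smarts: "[n]!@[CX4]",                          cut: [1, 2]}
  - {name: lactam_n_to_c,    smarts: "[NX3;$(N@[CX3]=O)]!@[CX4]",           cut: [1, 2]}
  - {name: biaryl,           smarts: "[c]!@[c]",                            cut: [1, 2]}
  - {name: sulfonamide,      smarts: "[NX3]!@[SX4](=[OX1])=[OX1]",          cut: [1, 2]}
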