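# Pharmacophore typing rules for the reduced pharmacophore graph.
# Each class lists SMARTS patterns; every atom of a match receives the bit.
# Hydrophobic and aromatic assignment is structural (carbon chains / rings)
# and handled in code; the four classes below are pattern-driven.
donor:
  - "[#7;!H0]"
  - "[#8;!H0]"
  - "[#16;!H0]"
acceptor:
  - "[#7;!$([#7+]);!$([NX3](=O)=O)]"
  - "[#8;!$([OX1]=[NX3])]"
positive:
  - "[*;+]"
  - "[NX3;H2;!$(NC=O)]"
negative:
  - "[*;-]"
  - "[CX3](=O)[OX2H1]"
  - "[SX4](=O)(=O)[OX2H]"
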