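"""Batched RDKit helper for the redgraph R package.

Reads one JSON request from argv[1], writes one JSON response to argv[2].
All molecule indices in the response are 0-based; the R side shifts them.
"""
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import BRICS, Draw
from rdkit.Chem.Draw import rdMolDraw2D

RDLogger.DisableLog("rdApp.*")

HYB = {
    Chem.HybridizationType.SP: "SP",
    Chem.HybridizationType.SP2: "SP2",
    Chem.HybridizationType.SP3: "SP3",
}
BOND_ORDER = {
    Chem.BondType.SINGLE: 1,
    Chem.BondType.DOUBLE: 2,
    Chem.BondType.TRIPLE: 3,
    Chem.BondType.AROMATIC: 4,
}


def mol_from_smiles(smi):
    try:
        return Chem.MolFromSmiles(smi)
    except Exception:
        return None


def op_parse(req):
    out = []
    for smi in req["smiles"]:
        mol = mol_from_smiles(smi)
        if mol is None or mol.GetNumAtoms() == 0:
            out.append({"ok": False})
            continue
        canonical = Chem.MolToSmiles(mol)
        # re-parse from the canonical string so atom order is canonical
        mol = Chem.MolFromSmiles(canonical)
        atoms = []
        for a in mol.GetAtoms():
            atoms.append({
                "el": a.GetSymbol(),
                "deg": a.GetDegree(),
                "chg": a.GetFormalCharge(),
                "arom": bool(a.GetIsAromatic()),
                "hyb": HYB.get(a.GetHybridization(), "other"),
                "nh": a.GetTotalNumHs(),
                "ring": a.IsInRing(),
            })
        bonds = []
        for b in mol.GetBonds():
            bonds.append({
                "a1": b.GetBeginAtomIdx(),
                "a2": b.GetEndAtomIdx(),
                "order": BOND_ORDER.get(b.GetBondType(), 0),
                "arom": bool(b.GetIsAromatic()),
                "conj": bool(b.GetIsConjugated()),
                "ring": b.IsInRing(),
            })
        rings = [list(r) for r in Chem.GetSymmSSSR(mol)]
        out.append({
            "ok": True,
            "canonical": canonical,
            "natoms": mol.GetNumAtoms(),
            "nbonds": mol.GetNumBonds(),
            "nfrag": len(Chem.GetMolFrags(mol)),
            "atoms": atoms,
            "bonds": bonds,
            "rings": rings,
        })
    return out


def op_match(req):
    """For each molecule x pattern: list of matched atom-index tuples."""
    pats = []
    for sma in req["smarts"]:
        p = Chem.MolFromSmarts(sma)
        if p is None:
            raise ValueError("invalid SMARTS: %s" % sma)
        pats.append(p)
    out = []
    maxm = int(req.get("max_matches", 256))
    for smi in req["smiles"]:
        mol = mol_from_smiles(smi)
        if mol is None:
            out.append(None)
            continue
        row = []
        for p in pats:
            ms = mol.GetSubstructMatches(p, uniquify=True, maxMatches=maxm)
            row.append([list(m) for m in ms])
        out.append(row)
    return out


def op_frag_smiles(req):
    """Canonical SMILES for atom subsets of parent molecules."""
    mols = {}
    out = []
    for smi, atoms in zip(req["smiles"], req["atomsets"]):
        if smi not in mols:
            mols[smi] = mol_from_smiles(smi)
        mol = mols[smi]
        if mol is None:
            out.append(None)
            continue
        try:
            frag = Chem.MolFragmentToSmiles(mol, atomsToUse=list(atoms),
                                            canonical=True)
        except Exception:
            frag = None
        out.append(frag)
    return out


def op_brics(req):
    out = []
    for smi in req["smiles"]:
        mol = mol_from_smiles(smi)
        if mol is None:
            out.append(None)
            continue
        bonds = [list(b[0]) for b in BRICS.FindBRICSBonds(mol)]
        out.append(bonds)
    return out


def op_depict(req):
    mol = mol_from_smiles(req["smiles"])
    if mol is None:
        return {"ok": False}
    w = [float(x) for x in req["weights"]]
    highlight = list(range(mol.GetNumAtoms()))
    colors = {i: (1.0 - 0.85 * w[i], 1.0, 1.0 - 0.85 * w[i])
              for i in highlight}
    d = rdMolDraw2D.MolDraw2DSVG(int(req.get("width", 450)),
                                 int(req.get("height", 350)))
    rdMolDraw2D.PrepareAndDrawMolecule(
        d, mol, highlightAtoms=highlight, highlightAtomColors=colors,
        highlightBonds=[])
    d.FinishDrawing()
    return {"ok": True, "svg": d.GetDrawingText()}


OPS = {
    "parse": op_parse,
    "match": op_match,
    "frag_smiles": op_frag_smiles,
    "brics": op_brics,
    "depict": op_depict,
}


def main():
    with open(sys.argv[1]) as fh:
        req = json.load(fh)
    res = OPS[req["op"]](req)
    with open(sys.argv[2], "w") as fh:
        json.dump(res, fh)


if __name__ == "__main__":
    main()
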