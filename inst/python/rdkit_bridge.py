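"""Batch molecule perception helper.

Reads a JSON request on stdin:
  {"smiles": [...], "seed": int, "coords": bool, "descriptors": int (0 = none),
   "scaffold": bool}
and writes a JSON response on stdout with one record per input SMILES.

All heavy lifting (aromaticity perception, UFF-optimized conformers,
Bemis-Murcko scaffolds, physicochemical descriptors) is done by RDKit; the
R side only consumes plain arrays. Hydrogens are implicit: records describe
the heavy-atom graph, with attached-H counts as an atom attribute.
"""

import json
import math
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, Descriptors
from rdkit.Chem.Scaffolds import MurckoScaffold

RDLogger.DisableLog("rdApp.*")

_ORDER = {
    Chem.BondType.SINGLE: 1.0,
    Chem.BondType.AROMATIC: 1.5,
    Chem.BondType.DOUBLE: 2.0,
    Chem.BondType.TRIPLE: 3.0,
}


def descriptor_functions(n):
    pairs = sorted(Descriptors.descList, key=lambda t: t[0])
    return pairs[:n]


def atom_record(mol):
    ring_info = mol.GetRingInfo()
    rec = {
        "element": [], "charge": [], "degree": [], "aromatic": [],
        "in_ring": [], "ring3": [], "ring4": [], "ring5": [], "ring6": [],
        "num_h": [],
    }
    for a in mol.GetAtoms():
        rec["element"].append(a.GetSymbol())
        rec["charge"].append(a.GetFormalCharge())
        rec["degree"].append(a.GetDegree())
        rec["aromatic"].append(bool(a.GetIsAromatic()))
        rec["in_ring"].append(bool(a.IsInRing()))
        for k in (3, 4, 5, 6):
            rec["ring%d" % k].append(bool(ring_info.IsAtomInRingOfSize(a.GetIdx(), k)))
        rec["num_h"].append(a.GetTotalNumHs())
    return rec


def bond_records(mol):
    out = []
    for b in mol.GetBonds():
        order = _ORDER.get(b.GetBondType())
        out.append({
            "i": b.GetBeginAtomIdx(), "j": b.GetEndAtomIdx(),
            "order": order if order is not None else -1.0,
            "aromatic": bool(b.GetIsAromatic()),
            "conjugated": bool(b.GetIsConjugated()),
            "in_ring": bool(b.IsInRing()),
        })
    return out


def embed_coords(mol, seed):
    """UFF-optimized single conformer; returns (coords, ok)."""
    mh = Chem.AddHs(mol)
    cid = AllChem.EmbedMolecule(mh, randomSeed=seed)
    if cid < 0:
        cid = AllChem.EmbedMolecule(mh, randomSeed=seed, useRandomCoords=True)
    if cid < 0:
        return None, False
    try:
        AllChem.UFFOptimizeMolecule(mh)
    except Exception:
        return None, False
    conf = mh.GetConformer()
    n_heavy = mol.GetNumAtoms()  # AddHs appends H's after the heavy atoms
    coords = []
    for idx in range(n_heavy):
        p = conf.GetAtomPosition(idx)
        coords.append([p.x, p.y, p.z])
    return coords, True


def process(smi, req, desc_fns):
    mol = Chem.MolFromSmiles(smi)
    if mol is None:
        return {"ok": False, "error": "unparsable SMILES: %r" % smi}
    kept_fragment = False
    frags = Chem.GetMolFrags(mol, asMols=True, sanitizeFrags=True)
    if len(frags) > 1:
        mol = max(frags, key=lambda m: m.GetNumAtoms())
        kept_fragment = True
    rec = {
        "ok": True,
        "canonical": Chem.MolToSmiles(mol),
        "kept_fragment": kept_fragment,
        "n_rings": mol.GetRingInfo().NumRings(),
        "atoms": atom_record(mol),
        "bonds": bond_records(mol),
    }
    if req.get("coords"):
        coords, ok = embed_coords(mol, int(req.get("seed", 1)))
        rec["coords"] = coords
        rec["embed_ok"] = ok
    if req.get("scaffold"):
        try:
            rec["scaffold"] = MurckoScaffold.MurckoScaffoldSmiles(mol=mol)
        except Exception:
            rec["scaffold"] = ""
    if desc_fns:
        vals = []
        for _, fn in desc_fns:
            try:
                v = float(fn(mol))
            except Exception:
                v = 0.0
            if not math.isfinite(v):
                v = 0.0
            vals.append(v)
        rec["descriptors"] = vals
    return rec


def process_sdf(path, req, desc_fns):
    """SDF V2000 records; stored 3D coordinates are used as-is."""
    out = []
    for mol in Chem.SDMolSupplier(path, removeHs=True):
        if mol is None:
            out.append({"ok": False, "error": "unreadable SDF record"})
            continue
        rec = {
            "ok": True,
            "canonical": Chem.MolToSmiles(mol),
            "kept_fragment": False,
            "n_rings": mol.GetRingInfo().NumRings(),
            "atoms": atom_record(mol),
            "bonds": bond_records(mol),
        }
        if mol.GetNumConformers() > 0:
            conf = mol.GetConformer()
            rec["coords"] = [[conf.GetAtomPosition(i).x,
                              conf.GetAtomPosition(i).y,
                              conf.GetAtomPosition(i).z]
                             for i in range(mol.GetNumAtoms())]
            rec["embed_ok"] = True
        if req.get("scaffold"):
            try:
                rec["scaffold"] = MurckoScaffold.MurckoScaffoldSmiles(mol=mol)
            except Exception:
                rec["scaffold"] = ""
        out.append(rec)
    return out


def main():
    req = json.load(sys.stdin)
    n_desc = int(req.get("descriptors", 0))
    desc_fns = descriptor_functions(n_desc) if n_desc > 0 else []
    if req.get("sdf_path"):
        mols = process_sdf(req["sdf_path"], req, desc_fns)
    else:
        mols = [process(s, req, desc_fns) for s in req["smiles"]]
    out = {
        "available_descriptors": len(Descriptors.descList),
        "descriptor_names": [name for name, _ in desc_fns],
        "mols": mols,
    }
    json.dump(out, sys.stdout)


if __name__ == "__main__":
    main()
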