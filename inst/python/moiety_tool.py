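"""RDKit worker for the moietherm R package.

Reads one JSON request on stdin, writes one JSON response on stdout.
Operations:
  parse        -- parse InChI/SMILES, canonicalize, report atom bookkeeping
  decompose    -- per-atom bonding-environment SMILES at given radii
  canonical    -- re-canonicalize fragment keys (idempotence checks)

The molecular graph is handled with implicit hydrogens throughout; environment
keys are canonical SMILES of the induced subgraph on all atoms within `radius`
bonds of the centre atom (every bond among those atoms is kept, including ring
closures between peripheral atoms).
"""
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import rdMolDescriptors
import rdkit

RDLogger.DisableLog("rdApp.*")

# organic subset accepted; anything else is treated as a metal/unsupported atom
ALLOWED_Z = {1, 5, 6, 7, 8, 9, 14, 15, 16, 17, 34, 35, 53}


def _mol_from_structure(structure):
    """Return (mol, error_class, message). InChI detected by prefix."""
    if structure.startswith("InChI="):
        mol = Chem.MolFromInchi(structure, sanitize=False, treatWarningAsError=False)
        kind = "InChI"
    else:
        mol = Chem.MolFromSmiles(structure, sanitize=False)
        kind = "SMILES"
    if mol is None:
        return None, "parse", "could not parse %s string" % kind
    # wildcard / repeat-unit atoms (polymers) and metals are rejected up front
    for atom in mol.GetAtoms():
        z = atom.GetAtomicNum()
        if z == 0:
            return None, "unsupported", "structure contains a wildcard/repeat-unit atom"
        if z not in ALLOWED_Z:
            return None, "unsupported", (
                "structure contains unsupported atom '%s' (metals and "
                "organometallics are not handled)" % atom.GetSymbol())
    try:
        Chem.SanitizeMol(mol)
    except Exception as exc:  # valence and kekulization failures
        return None, "valence", "sanitization failed: %s" % exc
    Chem.AssignStereochemistry(mol, cleanIt=True, force=True)
    return mol, None, None


def _element_counts(mol):
    counts = {}
    n_h = 0
    for atom in mol.GetAtoms():
        sym = atom.GetSymbol()
        counts[sym] = counts.get(sym, 0) + 1
        n_h += atom.GetTotalNumHs()
    if n_h:
        counts["H"] = counts.get("H", 0) + n_h
    return counts, n_h


def op_parse(req):
    out = []
    for entry in req["structures"]:
        structure = entry["structure"]
        mol, err_class, msg = _mol_from_structure(structure)
        if mol is None:
            out.append({"id": entry["id"], "ok": False,
                        "error_class": err_class, "error": msg})
            continue
        elements, n_h = _element_counts(mol)
        inchi = Chem.MolToInchi(mol)
        out.append({
            "id": entry["id"],
            "ok": True,
            "canonical_smiles": Chem.MolToSmiles(mol),
            "inchi": inchi,
            "heavy_atom_count": mol.GetNumHeavyAtoms(),
            "formal_charge": Chem.GetFormalCharge(mol),
            "num_protons": n_h,
            "elements": elements,
        })
    return {"results": out}


def _atoms_within(mol, idx, radius):
    seen = {idx}
    frontier = {idx}
    for _ in range(radius):
        nxt = set()
        for i in frontier:
            for nb in mol.GetAtomWithIdx(i).GetNeighbors():
                j = nb.GetIdx()
                if j not in seen:
                    nxt.add(j)
        seen |= nxt
        frontier = nxt
    return seen


def _environment_key(mol, idx, radius, stereo):
    atoms = _atoms_within(mol, idx, radius)
    bonds = [b.GetIdx() for b in mol.GetBonds()
             if b.GetBeginAtomIdx() in atoms and b.GetEndAtomIdx() in atoms]
    return Chem.MolFragmentToSmiles(
        mol, atomsToUse=sorted(atoms), bondsToUse=bonds or None,
        canonical=True, isomericSmiles=stereo)


def op_decompose(req):
    radii = [int(r) for r in req["radii"]]
    stereo = bool(req["stereo"])
    out = []
    for entry in req["molecules"]:
        mol, err_class, msg = _mol_from_structure(entry["structure"])
        if mol is None:
            out.append({"id": entry["id"], "ok": False,
                        "error_class": err_class, "error": msg})
            continue
        envs = {}
        for r in radii:
            envs[str(r)] = [_environment_key(mol, i, r, stereo)
                            for i in range(mol.GetNumAtoms())]
        out.append({"id": entry["id"], "ok": True, "environments": envs})
    return {"results": out}


def op_canonical(req):
    out = []
    for key in req["keys"]:
        mol = Chem.MolFromSmiles(key, sanitize=False)
        if mol is None:
            out.append(None)
            continue
        try:
            mol.UpdatePropertyCache(strict=False)
            Chem.FastFindRings(mol)
            out.append(Chem.MolToSmiles(mol))
        except Exception:
            out.append(None)
    return {"results": out}


OPS = {"parse": op_parse, "decompose": op_decompose, "canonical": op_canonical}


def main():
    req = json.load(sys.stdin)
    op = req.get("op")
    if op not in OPS:
        json.dump({"ok": False, "error": "unknown op %r" % op}, sys.stdout)
        return 1
    resp = OPS[op](req)
    resp["ok"] = True
    resp["toolkit"] = "rdkit"
    resp["toolkit_version"] = rdkit.__version__
    json.dump(resp, sys.stdout)
    return 0


if __name__ == "__main__":
    sys.exit(main())
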