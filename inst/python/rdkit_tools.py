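"""RDKit helper invoked by the R package as a subprocess.

Reads an SDF file and writes one JSON document with per-record results for
the requested tasks. Records that fail sanitization get null for the
sanitization-dependent tasks. Run:

    python rdkit_tools.py --sdf in.sdf --out out.json \
        --tasks sanitize,mmff,rings [--smarts alerts.tsv]
"""

import argparse
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem

RDLogger.DisableLog("rdApp.*")


def load_records(path):
    supplier = Chem.SDMolSupplier(path, sanitize=False, removeHs=False)
    mols, ok = [], []
    for raw in supplier:
        if raw is None:
            mols.append(None)
            ok.append(False)
            continue
        mol = Chem.Mol(raw)
        try:
            Chem.SanitizeMol(mol)  # default sanitization settings
            mols.append(mol)
            ok.append(True)
        except Exception:
            mols.append(None)
            ok.append(False)
    return mols, ok


def mmff_energy(mol):
    try:
        props = AllChem.MMFFGetMoleculeProperties(mol)
        if props is None:
            return None
        ff = AllChem.MMFFGetMoleculeForceField(mol, props)
        if ff is None:
            return None
        return ff.CalcEnergy()  # single point, no minimization
    except Exception:
        return None


def load_smarts(path):
    patterns = []
    with open(path) as fh:
        for line in fh:
            line = line.rstrip("\n")
            if not line or line.startswith("#"):
                continue
            name, smarts, source = line.split("\t")[:3]
            patt = Chem.MolFromSmarts(smarts)
            if patt is None:
                raise ValueError("unparseable SMARTS for %s: %s" % (name, smarts))
            patterns.append((name, source, patt))
    return patterns


def alert_names(mol, patterns):
    return [name for name, _src, patt in patterns if mol.HasSubstructMatch(patt)]


def ring_system_keys(mol):
    """Canonical SMILES keys of ring systems (rings merged on shared atoms
    or bonds), built from ring atoms and the in-ring bonds between them."""
    ri = mol.GetRingInfo()
    rings = [set(r) for r in ri.AtomRings()]
    if not rings:
        return []
    # merge rings sharing at least one atom (covers fused and spiro)
    merged = []
    for ring in rings:
        absorbed = ring
        rest = []
        for grp in merged:
            if grp & absorbed:
                absorbed = absorbed | grp
            else:
                rest.append(grp)
        merged = rest + [absorbed]
    keys = []
    for grp in merged:
        atoms = sorted(grp)
        bonds = [
            b.GetIdx()
            for b in mol.GetBonds()
            if b.GetBeginAtomIdx() in grp
            and b.GetEndAtomIdx() in grp
            and ri.NumBondRings(b.GetIdx()) > 0
        ]
        keys.append(
            Chem.MolFragmentToSmiles(mol, atomsToUse=atoms, bondsToUse=bonds, canonical=True)
        )
    return keys


def main(argv=None):
    ap = argparse.ArgumentParser()
    ap.add_argument("--sdf", required=True)
    ap.add_argument("--out", required=True)
    ap.add_argument("--tasks", required=True)
    ap.add_argument("--smarts")
    args = ap.parse_args(argv)

    tasks = args.tasks.split(",")
    mols, ok = load_records(args.sdf)
    result = {}
    if "sanitize" in tasks:
        result["sanitize"] = ok
    if "mmff" in tasks:
        result["mmff"] = [mmff_energy(m) if m is not None else None for m in mols]
    if "alerts" in tasks:
        patterns = load_smarts(args.smarts)
        result["alerts"] = [alert_names(m, patterns) if m is not None else None for m in mols]
    if "rings" in tasks:
        result["rings"] = [ring_system_keys(m) if m is not None else None for m in mols]
    with open(args.out, "w") as fh:
        json.dump(result, fh)
    return 0


if __name__ == "__main__":
    sys.exit(main())
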