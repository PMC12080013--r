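"""RDKit chemistry backend.

Reads a JSON request from argv[1], writes a JSON response to argv[2].

Request:
  {
    "smiles": ["CCO", ...],
    "embed3d": {"seed": 42} | null,
    "ecfp": {"radius": 2, "n_bits": 1024} | null,
    "fragments": true | false
  }

Response: {"molecules": [ {...} per input SMILES ]}.  Per-molecule fields:
  ok            bool (parse + sanitize succeeded)
  error         "parse" | "embed" | null
  canonical_smiles, scaffold_smiles
  n_atoms       heavy atom count
  atoms         list of {symbol, degree, charge, hyb, aromatic, n_hs,
                 in_ring, chiral}
  masses        heavy-atom masses (amu)
  bonds         list of [i, j] 0-based heavy-atom bond pairs
  coords2d      N x 2 (depiction layout)
  coords3d      N x 3 (ETKDG + MMFF heavy-atom positions) or null
  ecfp_bits     0-based indices of on bits
  brics_bonds   list of [i, j] bonds matched by BRICS cleavage rules
  murcko_atoms  0-based atom indices of the Bemis-Murcko scaffold
  fg_matches    list of 0-based atom-index lists, one per functional-group
                match (the attachment atom of each pattern is excluded)

All indices refer to the atom order of the canonical-SMILES molecule.
"""
import json
import os
import sys

from rdkit import Chem, RDConfig, RDLogger
from rdkit.Chem import AllChem, BRICS, FragmentCatalog
from rdkit.Chem.Scaffolds import MurckoScaffold

RDLogger.DisableLog("rdApp.*")

_FG_PARAMS = None


def fg_params():
    global _FG_PARAMS
    if _FG_PARAMS is None:
        fname = os.path.join(RDConfig.RDDataDir, "FunctionalGroups.txt")
        _FG_PARAMS = FragmentCatalog.FragCatParams(1, 6, fname)
    return _FG_PARAMS


def atom_record(atom):
    return {
        "symbol": atom.GetSymbol(),
        "degree": atom.GetDegree(),
        "charge": atom.GetFormalCharge(),
        "hyb": str(atom.GetHybridization()),
        "aromatic": bool(atom.GetIsAromatic()),
        "n_hs": atom.GetTotalNumHs(),
        "in_ring": bool(atom.IsInRing()),
        "chiral": str(atom.GetChiralTag()),
    }


def embed_coords3d(mol, seed):
    """ETKDG embedding + MMFF optimisation on the H-saturated molecule;
    returns heavy-atom coordinates (AddHs appends hydrogens, so the first
    N positions correspond to the original heavy atoms)."""
    molh = Chem.AddHs(mol)
    cid = AllChem.EmbedMolecule(molh, randomSeed=int(seed))
    if cid < 0:
        # retry with random coords, still seeded
        cid = AllChem.EmbedMolecule(
            molh, randomSeed=int(seed), useRandomCoords=True
        )
    if cid < 0:
        return None
    try:
        AllChem.MMFFOptimizeMolecule(molh)
    except Exception:
        pass
    pos = molh.GetConformer().GetPositions()
    n = mol.GetNumAtoms()
    return [[float(x) for x in pos[i]] for i in range(n)]


def process(smiles, embed3d, ecfp, want_frags, smarts=None):
    rec = {"ok": False, "error": None}
    mol = Chem.MolFromSmiles(smiles)
    if mol is None or mol.GetNumAtoms() == 0:
        rec["error"] = "parse"
        return rec
    can = Chem.MolToSmiles(mol)
    mol = Chem.MolFromSmiles(can)  # canonical atom order everywhere
    rec["ok"] = True
    rec["canonical_smiles"] = can
    n = mol.GetNumAtoms()
    rec["n_atoms"] = n
    rec["atoms"] = [atom_record(a) for a in mol.GetAtoms()]
    rec["masses"] = [a.GetMass() for a in mol.GetAtoms()]
    rec["bonds"] = [
        [b.GetBeginAtomIdx(), b.GetEndAtomIdx()] for b in mol.GetBonds()
    ]
    AllChem.Compute2DCoords(mol)
    conf = mol.GetConformer()
    rec["coords2d"] = [
        [conf.GetAtomPosition(i).x, conf.GetAtomPosition(i).y]
        for i in range(n)
    ]
    try:
        rec["scaffold_smiles"] = MurckoScaffold.MurckoScaffoldSmiles(mol=mol)
    except Exception:
        rec["scaffold_smiles"] = ""

    if embed3d is not None:
        coords = embed_coords3d(mol, embed3d.get("seed", 0))
        if coords is None:
            rec["ok"] = False
            rec["error"] = "embed"
            return rec
        rec["coords3d"] = coords

    if ecfp is not None:
        fp = AllChem.GetMorganFingerprintAsBitVect(
            mol, int(ecfp.get("radius", 2)), nBits=int(ecfp.get("n_bits", 1024))
        )
        rec["ecfp_bits"] = list(fp.GetOnBits())

    if want_frags:
        rec["brics_bonds"] = [
            [int(b[0][0]), int(b[0][1])] for b in BRICS.FindBRICSBonds(mol)
        ]
        try:
            scaf = MurckoScaffold.GetScaffoldForMol(mol)
            if scaf is not None and scaf.GetNumAtoms() > 0:
                match = mol.GetSubstructMatch(scaf)
                rec["murcko_atoms"] = list(match)
            else:
                rec["murcko_atoms"] = []
        except Exception:
            rec["murcko_atoms"] = []
        params = fg_params()
        matches = []
        for i in range(params.GetNumFuncGroups()):
            patt = params.GetFuncGroup(i)
            for m in mol.GetSubstructMatches(patt):
                # first pattern atom is the attachment point, not the group
                if len(m) > 1:
                    matches.append(list(m[1:]))
        rec["fg_matches"] = matches

    if smarts:
        counts = []
        for patt in smarts:
            q = Chem.MolFromSmarts(patt)
            counts.append(len(mol.GetSubstructMatches(q)) if q else -1)
        rec["smarts_counts"] = counts
    return rec


def main():
    with open(sys.argv[1]) as fh:
        req = json.load(fh)
    embed3d = req.get("embed3d")
    ecfp = req.get("ecfp")
    want_frags = bool(req.get("fragments", False))
    smarts = req.get("smarts")
    out = {
        "molecules": [
            process(s, embed3d, ecfp, want_frags, smarts)
            for s in req["smiles"]
        ]
    }
    with open(sys.argv[2], "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
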