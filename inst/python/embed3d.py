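"""Deterministic single-conformer 3D embedding.

Reads tab-separated "SMILES\tid" lines on stdin, embeds one conformer per
molecule with ETKDGv3 at the seed given as argv[1] followed by MMFF94
cleanup, and prints a JSON list of {id, ok, coords} records where coords
holds heavy-atom coordinates in input (SMILES) atom order.
"""
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem

RDLogger.DisableLog("rdApp.*")


def embed(smiles, seed):
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        return None
    n_heavy = mol.GetNumAtoms()
    molh = Chem.AddHs(mol)
    params = AllChem.ETKDGv3()
    params.randomSeed = seed
    if AllChem.EmbedMolecule(molh, params) < 0:
        return None
    try:
        AllChem.MMFFOptimizeMolecule(molh, maxIters=2000)
    except Exception:
        pass
    conf = molh.GetConformer()
    return [
        [conf.GetAtomPosition(i).x, conf.GetAtomPosition(i).y, conf.GetAtomPosition(i).z]
        for i in range(n_heavy)
    ]


def main():
    seed = int(sys.argv[1]) if len(sys.argv) > 1 else 1
    out = []
    for line in sys.stdin.read().splitlines():
        if not line.strip():
            continue
        smiles, _, mid = line.partition("\t")
        coords = embed(smiles, seed)
        rec = {"id": mid, "ok": coords is not None}
        if coords is not None:
            rec["coords"] = coords
        out.append(rec)
    json.dump(out, sys.stdout)


if __name__ == "__main__":
    main()
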