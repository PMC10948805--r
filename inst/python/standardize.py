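"""Batched SMILES standardization service.

Reads a JSON array of SMILES strings (argv[1]), writes a JSON array of
per-structure results (argv[2]). Invalid SMILES yield {"ok": false} rather
than an error, so the caller decides how parse failures are handled.
"""
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem.Descriptors import MolWt
from rdkit.Chem.inchi import MolToInchiKey

RDLogger.DisableLog("rdApp.*")

BOND_SYMBOL = {"SINGLE": "-", "DOUBLE": "=", "TRIPLE": "#", "AROMATIC": ":"}


def standardize(smiles):
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        return {"ok": False, "smiles": smiles}
    return {
        "ok": True,
        "smiles": smiles,
        "canonical": Chem.MolToSmiles(mol),
        "inchikey": MolToInchiKey(mol),
        "mw": MolWt(mol),
        "n_atoms": mol.GetNumAtoms(),
        "charges": [a.GetFormalCharge() for a in mol.GetAtoms()],
        "atom_symbol": [a.GetSymbol() for a in mol.GetAtoms()],
        "atom_aromatic": [int(a.GetIsAromatic()) for a in mol.GetAtoms()],
        "bond_from": [b.GetBeginAtomIdx() + 1 for b in mol.GetBonds()],
        "bond_to": [b.GetEndAtomIdx() + 1 for b in mol.GetBonds()],
        "bond_order": [
            BOND_SYMBOL.get(str(b.GetBondType()), "-") for b in mol.GetBonds()
        ],
    }


def main():
    with open(sys.argv[1]) as fh:
        smiles_list = json.load(fh)
    out = [standardize(s) for s in smiles_list]
    with open(sys.argv[2], "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
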