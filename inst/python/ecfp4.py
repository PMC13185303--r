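"""Sparse ECFP4 (Morgan radius 2) feature sets + heavy-atom counts via RDKit.

Input : SMILES file, one molecule per line, "SMILES<TAB>id".
Output: one line per molecule, "id<TAB>heavy_atoms<TAB>f1,f2,...".
Lines that fail to parse are reported as "#SKIP<TAB>id" on stdout.
"""
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem

RDLogger.DisableLog("rdApp.*")


def main(path):
    gen = AllChem.GetMorganGenerator(radius=2)
    with open(path) as fh:
        for line in fh:
            line = line.rstrip("\n")
            if not line:
                continue
            fields = line.split("\t")
            smiles = fields[0]
            mol_id = fields[1] if len(fields) > 1 else smiles
            mol = Chem.MolFromSmiles(smiles)
            if mol is None:
                print("#SKIP\t%s" % mol_id)
                continue
            fp = gen.GetSparseCountFingerprint(mol)
            feats = sorted(fp.GetNonzeroElements())
            print("%s\t%d\t%s" % (mol_id, mol.GetNumHeavyAtoms(),
                                  ",".join(str(f) for f in feats)))


if __name__ == "__main__":
    main(sys.argv[1])
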