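"""Batch QED / synthetic-accessibility scoring.

Reads one SMILES per line on stdin, writes tab-separated
``smiles<TAB>qed<TAB>sascore`` per line on stdout (``NA`` where the molecule
cannot be parsed). Uses the published QED implementation and the published
synthetic-accessibility score from the RDKit contrib collection.
"""
import sys
import os

from rdkit import Chem, RDLogger
from rdkit.Chem import QED, RDConfig

RDLogger.DisableLog("rdApp.*")
sys.path.append(os.path.join(RDConfig.RDContribDir, "SA_Score"))
import sascorer  # noqa: E402


def main():
    for line in sys.stdin:
        smi = line.strip()
        if not smi:
            continue
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            print(f"{smi}\tNA\tNA")
            continue
        try:
            q = QED.qed(mol)
            s = sascorer.calculateScore(mol)
            print(f"{smi}\t{q:.6f}\t{s:.6f}")
        except Exception:
            print(f"{smi}\tNA\tNA")


if __name__ == "__main__":
    main()
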