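"""Cheminformatics backend for the pkcascade R package.

Reads SMILES (one per line) on stdin, writes tab-separated results on
stdout.  Subcommands:

  standardize   -> status, std_smiles, mol_weight
  fingerprint   -> status, space-separated indices of on bits (2048-bit
                   Morgan fingerprint, radius 2)
  descriptors   -> header row, then status + one value per 2D descriptor

All errors are reported per-row via the status column ("ok"/"error");
the process always exits 0 unless the subcommand itself is unknown.
"""
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, Descriptors
from rdkit.Chem.MolStandardize import rdMolStandardize

RDLogger.DisableLog("rdApp.*")

FP_BITS = 2048
FP_RADIUS = 2

# Protonation state rules for pH 7.4: acids with pKa well below 7.4 are
# deprotonated, basic amines/amidines/guanidines (pKa well above 7.4)
# are protonated.  Patterns are applied exhaustively and are idempotent
# (a transformed site no longer matches its pattern).
_ACID_SMARTS = [
    "[CX3](=O)[OX2H1]",          # carboxylic acid
    "[SX4](=O)(=O)[OX2H1]",      # sulfonic acid
    "[PX4](=O)([OX2H1])",        # phosphonic/phosphoric first OH
    "[c]1[n][n][n][nH]1",        # 1H-tetrazole (acidic NH)
]
_BASE_SMARTS = [
    # aliphatic amine: sp3 N, not amide/sulfonamide/aniline/nitro,
    # not adjacent to carbonyl or aromatic ring, no existing charge
    "[NX3;H2,H1,H0;+0;!$(N-[a]);!$(N-C=[O,N,S]);!$(N-S(=O)=O);!$(N-N=O);!$(N~[!#6;!#1])]",
    "[NX2;+0]=[CX3][NX3;+0]",    # amidine / guanidine (protonate sp2 N)
]


def _protonate_ph74(mol):
    rw = Chem.RWMol(mol)
    changed = False
    for smarts in _ACID_SMARTS:
        patt = Chem.MolFromSmarts(smarts)
        for match in rw.GetSubstructMatches(patt):
            for idx in match:
                atom = rw.GetAtomWithIdx(idx)
                if atom.GetAtomicNum() in (7, 8) and atom.GetTotalNumHs() >= 1 \
                        and atom.GetFormalCharge() == 0:
                    atom.SetFormalCharge(-1)
                    atom.SetNumExplicitHs(atom.GetTotalNumHs() - 1)
                    atom.SetNoImplicit(True)
                    changed = True
                    break
    for smarts in _BASE_SMARTS:
        patt = Chem.MolFromSmarts(smarts)
        for match in rw.GetSubstructMatches(patt):
            atom = rw.GetAtomWithIdx(match[0])
            if atom.GetFormalCharge() == 0 and atom.GetAtomicNum() == 7:
                atom.SetFormalCharge(1)
                atom.SetNumExplicitHs(atom.GetTotalNumHs() + 1)
                atom.SetNoImplicit(True)
                changed = True
    if changed:
        mol = rw.GetMol()
        Chem.SanitizeMol(mol)
    return mol


_normalizer = rdMolStandardize.Normalizer()
_fragmenter = rdMolStandardize.LargestFragmentChooser()
_tautomerizer = rdMolStandardize.TautomerEnumerator()
_tautomerizer.SetMaxTautomers(512)


def standardize_one(smi):
    mol = Chem.MolFromSmiles(smi)
    if mol is None:
        raise ValueError("unparsable SMILES")
    mol = rdMolStandardize.Cleanup(mol)
    mol = _normalizer.normalize(mol)
    mol = _fragmenter.choose(mol)
    mol = _tautomerizer.Canonicalize(mol)
    mol = _protonate_ph74(mol)
    return Chem.MolToSmiles(mol), Descriptors.ExactMolWt(mol)


def cmd_standardize(lines):
    for smi in lines:
        try:
            std, mw = standardize_one(smi)
            sys.stdout.write("ok\t%s\t%.6f\n" % (std, mw))
        except Exception:
            sys.stdout.write("error\t\tNA\n")


def cmd_fingerprint(lines):
    for smi in lines:
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            sys.stdout.write("error\t\n")
            continue
        fp = AllChem.GetMorganFingerprintAsBitVect(mol, FP_RADIUS, nBits=FP_BITS)
        bits = " ".join(str(b + 1) for b in fp.GetOnBits())  # 1-based for R
        sys.stdout.write("ok\t%s\n" % bits)


def cmd_descriptors(lines):
    names = [n for n, _ in Descriptors.descList]
    sys.stdout.write("status\t" + "\t".join(names) + "\n")
    calc = dict(Descriptors.descList)
    for smi in lines:
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            sys.stdout.write("error" + "\tNA" * len(names) + "\n")
            continue
        vals = []
        for n in names:
            try:
                v = calc[n](mol)
                if v != v or v in (float("inf"), float("-inf")):
                    vals.append("NA")
                else:
                    vals.append(repr(float(v)))
            except Exception:
                vals.append("NA")
        sys.stdout.write("ok\t" + "\t".join(vals) + "\n")


def main():
    if len(sys.argv) < 2 or sys.argv[1] not in ("standardize", "fingerprint",
                                                "descriptors"):
        sys.stderr.write("usage: chem_tools.py standardize|fingerprint|descriptors\n")
        return 2
    lines = [ln.strip() for ln in sys.stdin if ln.strip()]
    {"standardize": cmd_standardize,
     "fingerprint": cmd_fingerprint,
     "descriptors": cmd_descriptors}[sys.argv[1]](lines)
    return 0


if __name__ == "__main__":
    sys.exit(main())
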