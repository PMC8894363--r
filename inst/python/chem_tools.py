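"""RDKit worker invoked by the R package in batch mode.

Modes:
  props <infile> <outfile>
      infile: one SMILES per line.
      outfile: TSV, one row per input line, columns
        ok(0/1)  canonical  elements(space-sep)  sf56(0/1)  scaffold
      Standardization: parse -> sanitize/cleanup -> largest fragment ->
      uncharge -> canonical SMILES (MolVS-style default flow).
  sdf <infile> <outfile> <logS-aliases,comma-sep>
      outfile: JSON lines {smiles, logS, props:{...}} per molecule block.
"""
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem.MolStandardize import rdMolStandardize
from rdkit.Chem.Scaffolds import MurckoScaffold

RDLogger.DisableLog("rdApp.*")

_LF = rdMolStandardize.LargestFragmentChooser()
_UN = rdMolStandardize.Uncharger()


def standardize(smiles):
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        return None
    try:
        mol = rdMolStandardize.Cleanup(mol)
        mol = _LF.choose(mol)
        mol = _UN.uncharge(mol)
        Chem.SanitizeMol(mol)
    except Exception:
        return None
    return mol


def sulfur_pentafluoride(mol):
    for atom in mol.GetAtoms():
        if atom.GetSymbol() != "S":
            continue
        n_f = sum(1 for nb in atom.GetNeighbors() if nb.GetSymbol() == "F")
        if n_f >= 5:
            return True
    return False


def props(infile, outfile):
    with open(infile) as fin, open(outfile, "w") as fout:
        for line in fin:
            smi = line.rstrip("\n")
            mol = standardize(smi)
            if mol is None:
                fout.write("0\t\t\t0\t\n")
                continue
            can = Chem.MolToSmiles(mol)
            # element and SF5/SF6 checks look at every atom of the input
            # structure (all fragments), not only the standardized parent:
            # a blacklisted counter-ion must still trigger the filter
            raw = Chem.MolFromSmiles(smi)
            ref = raw if raw is not None else mol
            elements = sorted({a.GetSymbol() for a in ref.GetAtoms()})
            sf = int(sulfur_pentafluoride(ref))
            try:
                scaf = MurckoScaffold.MurckoScaffoldSmiles(mol=mol)
            except Exception:
                scaf = ""
            fout.write("1\t%s\t%s\t%d\t%s\n" % (can, " ".join(elements), sf, scaf))


def sdf(infile, outfile, aliases):
    aliases = aliases.split(",")
    supplier = Chem.SDMolSupplier(infile, sanitize=False)
    with open(outfile, "w") as fout:
        for mol in supplier:
            if mol is None:
                fout.write(json.dumps({"smiles": None, "logS": None, "props": {}}) + "\n")
                continue
            pd = mol.GetPropsAsDict()
            logs = None
            for a in aliases:
                if a in pd:
                    logs = str(pd[a])
                    break
            try:
                Chem.SanitizeMol(mol)
                smi = Chem.MolToSmiles(mol)
            except Exception:
                smi = None
            fout.write(json.dumps(
                {"smiles": smi, "logS": logs,
                 "props": {k: str(v) for k, v in pd.items()}}) + "\n")


def main(argv):
    mode = argv[1]
    if mode == "props":
        props(argv[2], argv[3])
    elif mode == "sdf":
        sdf(argv[2], argv[3], argv[4] if len(argv) > 4 else "LogS")
    else:
        raise SystemExit("unknown mode: %s" % mode)


if __name__ == "__main__":
    main(sys.argv)
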