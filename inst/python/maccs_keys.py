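"""166-key MACCS fingerprints for tfbench.

Reads molecules, writes one line per molecule: <id>\t<42-char hex> or
<id>\tNA\t<reason>. The hex string packs key bits 1..166 MSB-first in
4-bit chunks, padded with two trailing zero bits (168 bits = 42 hex chars).

Modes:
  maccs_keys.py smiles <file>      two-column TSV: id<TAB>smiles
  maccs_keys.py sdf <file> [prop]  SDF; id from property `prop` or mol title

Multi-component (dot-disconnected) structures are reported unavailable:
the similarity method is defined for single molecules, not mixtures.
"""
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import MACCSkeys

RDLogger.DisableLog("rdApp.*")


def fp_hex(mol):
    fp = MACCSkeys.GenMACCSKeys(mol)  # 167 bits, bit 0 unused
    bits = [0] * 168
    for b in fp.GetOnBits():
        if 1 <= b <= 166:
            bits[b - 1] = 1
    out = []
    for i in range(0, 168, 4):
        out.append("%x" % (bits[i] * 8 + bits[i + 1] * 4 + bits[i + 2] * 2 + bits[i + 3]))
    return "".join(out)


def emit(mol_id, smiles_or_mol, is_mol=False):
    if is_mol:
        mol = smiles_or_mol
    else:
        if "." in smiles_or_mol:
            print("%s\tNA\tmulti_component" % mol_id)
            return
        mol = Chem.MolFromSmiles(smiles_or_mol)
    if mol is None:
        print("%s\tNA\tunparseable" % mol_id)
        return
    if len(Chem.GetMolFrags(mol)) > 1:
        print("%s\tNA\tmulti_component" % mol_id)
        return
    try:
        print("%s\t%s" % (mol_id, fp_hex(mol)))
    except Exception:
        print("%s\tNA\tfingerprint_failed" % mol_id)


def main(argv):
    mode = argv[1]
    if mode == "smiles":
        with open(argv[2]) as fh:
            for line in fh:
                line = line.rstrip("\n")
                if not line or line.startswith("#"):
                    continue
                parts = line.split("\t")
                if len(parts) < 2:
                    continue
                emit(parts[0].strip(), parts[1].strip())
    elif mode == "sdf":
        prop = argv[3] if len(argv) > 3 else None
        supplier = Chem.SDMolSupplier(argv[2], sanitize=True)
        for i, mol in enumerate(supplier):
            if mol is None:
                print("sdf_record_%d\tNA\tunparseable" % (i + 1))
                continue
            if prop and mol.HasProp(prop):
                mol_id = mol.GetProp(prop)
            elif mol.HasProp("_Name") and mol.GetProp("_Name"):
                mol_id = mol.GetProp("_Name")
            else:
                mol_id = "sdf_record_%d" % (i + 1)
            emit(mol_id, mol, is_mol=True)
    else:
        sys.stderr.write("unknown mode: %s\n" % mode)
        return 2
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv))
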