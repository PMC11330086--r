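"""Structure-handling backend for the chemgroup R package.

Invoked as:  python chemtools.py <command> <input.json> <output.json>

Commands: parse_sdf, parse_smiles, standardize, fingerprints, descriptors, embed.
All molecule handling is RDKit; UMAP via umap-learn, t-SNE via scikit-learn.
Every command is deterministic given the seeds in its payload.
"""

import json
import sys

from rdkit import Chem, rdBase
from rdkit import RDLogger

RDLogger.DisableLog("rdApp.*")


def _read(path):
    with open(path, "r") as fh:
        return json.load(fh)


def _write(path, obj):
    with open(path, "w") as fh:
        json.dump(obj, fh)


# ---------------------------------------------------------------- parsing

def cmd_parse_sdf(payload):
    """Read an SDF file; unreadable mol-blocks become parse_ok=False records."""
    label_prop = payload.get("label_property")
    supplier = Chem.SDMolSupplier(payload["path"], sanitize=True, removeHs=True)
    records = []
    for i in range(len(supplier)):
        try:
            mol = supplier[i]
        except Exception:
            mol = None
        if mol is None:
            records.append({"index": i, "parse_ok": False, "smiles": None,
                            "label": None})
            continue
        label = None
        if label_prop is not None and mol.HasProp(label_prop):
            label = mol.GetProp(label_prop)
        records.append({"index": i, "parse_ok": True,
                        "smiles": Chem.MolToSmiles(mol), "label": label})
    return {"records": records, "n": len(supplier),
            "rdkit_version": rdBase.rdkitVersion}


def cmd_parse_smiles(payload):
    records = []
    for i, smi in enumerate(payload["smiles"]):
        mol = Chem.MolFromSmiles(smi) if smi else None
        records.append({"index": i, "parse_ok": mol is not None,
                        "smiles": Chem.MolToSmiles(mol) if mol else None})
    return {"records": records, "rdkit_version": rdBase.rdkitVersion}


# ---------------------------------------------------------- standardization

def _standardize_one(text, is_molblock, std):
    """QSAR-ready-style rule chain; returns (smiles, rules, reason)."""
    from rdkit.Chem.MolStandardize import rdMolStandardize

    if is_molblock:
        mol = Chem.MolFromMolBlock(text, sanitize=True, removeHs=True)
    else:
        mol = Chem.MolFromSmiles(text)
    if mol is None:
        return None, [], "unparseable_structure"
    rules = []

    # 1. largest organic fragment (salt / counterion removal)
    frags = Chem.GetMolFrags(mol, asMols=True, sanitizeFrags=False)
    if len(frags) > 1:
        mol = std["fragment"].choose(mol)
        rules.append("salt_removal")
    if not any(a.GetAtomicNum() == 6 for a in mol.GetAtoms()):
        return None, rules, "no_organic_fragment"

    # 2. charge neutralization (balanced zwitterions such as nitro are kept)
    before = Chem.MolToSmiles(mol)
    mol = std["uncharger"].uncharge(mol)
    if Chem.MolToSmiles(mol) != before:
        rules.append("neutralization")

    # 3. functional-group normalization (nitro to the charge-separated form)
    before = Chem.MolToSmiles(mol)
    mol = std["normalizer"].normalize(mol)
    if Chem.MolToSmiles(mol) != before:
        rules.append("nitro_normalization")

    # 4. canonical tautomer
    before = Chem.MolToSmiles(mol)
    try:
        mol = std["tautomer"].Canonicalize(mol)
    except Exception:
        return None, rules, "tautomer_failure"
    if Chem.MolToSmiles(mol) != before:
        rules.append("tautomer_canonicalization")

    # 5. stereochemistry removal
    before = Chem.MolToSmiles(mol)
    Chem.RemoveStereochemistry(mol)
    if Chem.MolToSmiles(mol) != before:
        rules.append("stereo_removal")

    # 6. valence check
    try:
        Chem.SanitizeMol(mol)
    except Exception:
        return None, rules, "uncorrectable_valence"

    return Chem.MolToSmiles(mol), rules, None


def cmd_standardize(payload):
    from rdkit.Chem.MolStandardize import rdMolStandardize

    chooser = rdMolStandardize.LargestFragmentChooser(preferOrganic=True)
    std = {
        "fragment": chooser,
        "uncharger": rdMolStandardize.Uncharger(),
        "normalizer": rdMolStandardize.Normalizer(),
        "tautomer": rdMolStandardize.TautomerEnumerator(),
    }
    is_molblock = bool(payload.get("is_molblock", False))
    out = []
    for text in payload["structures"]:
        smi, rules, reason = _standardize_one(text, is_molblock, std)
        out.append({"ok": smi is not None, "canonical_smiles": smi,
                    "applied_rules": rules, "reason": reason})
    return {"results": out,
            "tautomer_scheme": "rdkit_MolStandardize_TautomerEnumerator",
            "rdkit_version": rdBase.rdkitVersion}


# ------------------------------------------------------------ descriptors

def cmd_fingerprints(payload):
    from rdkit.Chem import AllChem, MACCSkeys

    family = payload["family"]
    radius = int(payload.get("radius", 3))
    n_bits = int(payload.get("n_bits", 2048))
    bits, failed = [], []
    for i, smi in enumerate(payload["smiles"]):
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            failed.append(i)
            bits.append(None)
            continue
        try:
            if family == "morgan":
                fp = AllChem.GetMorganFingerprintAsBitVect(mol, radius,
                                                           nBits=n_bits)
            elif family == "feat_morgan":
                fp = AllChem.GetMorganFingerprintAsBitVect(
                    mol, radius, nBits=n_bits, useFeatures=True)
            elif family == "maccs":
                fp = MACCSkeys.GenMACCSKeys(mol)
            else:
                raise ValueError("unknown fingerprint family: " + family)
        except Exception:
            failed.append(i)
            bits.append(None)
            continue
        s = fp.ToBitString()
        if family == "maccs":
            s = s[1:]  # key 0 is a placeholder; 166 informative keys remain
        bits.append(s)
    return {"bits": bits, "failed": failed,
            "rdkit_version": rdBase.rdkitVersion}


# The compact set pins 119 standard rdkit 2-D descriptors: all non-fragment
# descriptors minus composite/overflow-prone entries.
_COMPACT_EXCLUDE = {"Ipc", "AvgIpc", "qed", "SPS",
                    "MaxAbsPartialCharge", "MinAbsPartialCharge"}


def _descriptor_list(set_name):
    from rdkit.Chem import Descriptors

    pairs = list(Descriptors._descList)
    if set_name == "compact":
        pairs = [(n, f) for n, f in pairs
                 if not n.startswith("fr_") and n not in _COMPACT_EXCLUDE]
    elif set_name != "extended":
        raise ValueError("unknown descriptor set: " + set_name)
    return pairs


def cmd_descriptors(payload):
    import math

    pairs = _descriptor_list(payload["set"])
    names = [n for n, _ in pairs]
    values, failed = [], []
    for i, smi in enumerate(payload["smiles"]):
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            failed.append(i)
            values.append(None)
            continue
        row = []
        for _, fn in pairs:
            try:
                v = float(fn(mol))
            except Exception:
                v = float("nan")
            row.append(v if math.isfinite(v) else None)
        values.append(row)
    return {"names": names, "values": values, "failed": failed,
            "rdkit_version": rdBase.rdkitVersion}


# ------------------------------------------------------------- embeddings

def cmd_embed(payload):
    """Run a batch of 2-D embedding jobs on one shared matrix.

    Batching amortizes interpreter start-up and numba compilation across
    the trials of a tuning run.
    """
    import numpy as np

    X = np.asarray(payload["X"], dtype=float)
    out = []
    for job in payload["jobs"]:
        method = job["method"]
        params = job.get("params", {})
        seed = int(job.get("seed", 0))
        if method == "umap":
            import umap
            import warnings
            with warnings.catch_warnings():
                warnings.simplefilter("ignore")
                emb = umap.UMAP(
                    n_components=2,
                    n_neighbors=int(params.get("n_neighbors", 15)),
                    min_dist=float(params.get("min_dist", 0.1)),
                    random_state=seed, n_jobs=1,
                ).fit_transform(X)
        elif method == "tsne":
            from sklearn.manifold import TSNE
            emb = TSNE(
                n_components=2,
                perplexity=float(params.get("perplexity", 30.0)),
                random_state=seed, init="pca",
            ).fit_transform(X)
        else:
            raise ValueError("unknown embedding method: " + method)
        out.append(np.asarray(emb, dtype=float).tolist())
    return {"embeddings": out}


COMMANDS = {
    "parse_sdf": cmd_parse_sdf,
    "parse_smiles": cmd_parse_smiles,
    "standardize": cmd_standardize,
    "fingerprints": cmd_fingerprints,
    "descriptors": cmd_descriptors,
    "embed": cmd_embed,
}


def main(argv):
    if len(argv) != 4:
        sys.stderr.write("usage: chemtools.py <command> <in.json> <out.json>\n")
        return 2
    cmd, in_path, out_path = argv[1], argv[2], argv[3]
    if cmd not in COMMANDS:
        sys.stderr.write("unknown command: %s\n" % cmd)
        return 2
    payload = _read(in_path)
    try:
        result = COMMANDS[cmd](payload)
    except Exception as exc:  # surfaced to R as a structured error
        _write(out_path, {"error": "%s: %s" % (type(exc).__name__, exc)})
        return 1
    _write(out_path, result)
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv))
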