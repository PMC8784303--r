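"""Convert a FieldTrip TFR struct in a MAT file (v7 or v7.3) to a JSON
header plus a raw float64 stream (C order) for consumption by R."""
import json
import sys

import numpy as np

REQUIRED = ("powspctrm", "label", "freq", "time")


def _from_scipy(path):
    from scipy.io import loadmat

    m = loadmat(path, squeeze_me=False, struct_as_record=False)
    vars_ = {k: v for k, v in m.items() if not k.startswith("__")}
    # struct variable (possibly wrapped in an object/record array) or loose
    # top-level variables
    for v in vars_.values():
        obj = v
        while isinstance(obj, np.ndarray) and obj.size == 1 and (
            obj.dtype == object or obj.dtype.names
        ):
            if obj.dtype.names:
                break
            obj = obj.flat[0]
        d = None
        if hasattr(obj, "_fieldnames"):
            d = {f: getattr(obj, f) for f in obj._fieldnames}
        elif isinstance(obj, np.ndarray) and obj.dtype.names:
            rec = obj.flat[0]
            d = {f: rec[f] for f in obj.dtype.names}
        if d is not None and all(f in d for f in REQUIRED):
            return d
    if all(f in vars_ for f in REQUIRED):
        return vars_
    raise KeyError(
        "no FieldTrip TFR struct found; need fields " + ", ".join(REQUIRED)
    )


def _from_h5py(path):
    import h5py

    def read_labels(f, ds):
        out = []
        for ref in np.asarray(ds).ravel():
            out.append("".join(chr(c) for c in np.asarray(f[ref]).ravel()))
        return out

    with h5py.File(path, "r") as f:
        grp = None
        for k in f.keys():
            if k.startswith("#"):
                continue
            node = f[k]
            if isinstance(node, h5py.Group) and all(r in node for r in REQUIRED):
                grp = node
                break
        if grp is None and all(r in f for r in REQUIRED):
            grp = f
        if grp is None:
            raise KeyError("no FieldTrip TFR struct found in v7.3 file")
        # MATLAB HDF5 arrays come out transposed (Fortran on disk)
        pow_ = np.asarray(grp["powspctrm"]).T
        d = {
            "powspctrm": pow_,
            "freq": np.asarray(grp["freq"]).ravel(),
            "time": np.asarray(grp["time"]).ravel(),
            "label": read_labels(f, grp["label"]),
            "trialinfo": (
                np.asarray(grp["trialinfo"]).T if "trialinfo" in grp else None
            ),
        }
    return d


def main(mat_path, out_stem):
    try:
        d = _from_scipy(mat_path)
    except NotImplementedError:  # v7.3 -> HDF5
        d = _from_h5py(mat_path)

    pow_ = np.asarray(d["powspctrm"], dtype=np.float64)
    if pow_.ndim != 4:
        raise ValueError(f"powspctrm must be 4-D, got shape {pow_.shape}")
    labels = d["label"]
    if not isinstance(labels, list):
        labels = [
            str(np.asarray(x).ravel()[0]) for x in np.asarray(labels).ravel()
        ]
    ti = d.get("trialinfo")
    ti = None if ti is None else np.atleast_2d(np.asarray(ti, dtype=float))
    header = {
        "dims": [int(x) for x in pow_.shape],
        "freq": np.asarray(d["freq"], dtype=float).ravel().tolist(),
        "time": np.asarray(d["time"], dtype=float).ravel().tolist(),
        "label": labels,
        "trialinfo": [] if ti is None or ti.size == 0 else ti.tolist(),
    }
    with open(out_stem + ".json", "w") as fh:
        json.dump(header, fh)
    pow_.astype(np.float64).tofile(out_stem + ".bin")


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
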