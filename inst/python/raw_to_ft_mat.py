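"""Build a minimal FieldTrip TFR struct MAT file from the JSON header +
raw float64 stream emitted by R (C order)."""
import json
import sys

import numpy as np
from scipy.io import savemat


def main(stem, mat_path):
    with open(stem + ".json") as fh:
        hdr = json.load(fh)
    dims = tuple(int(x) for x in hdr["dims"])
    pow_ = np.fromfile(stem + ".bin", dtype=np.float64).reshape(dims)
    label = np.array(
        [[np.array([s])] for s in hdr["label"]], dtype=object
    )  # cell column of strings
    struct = {
        "powspctrm": pow_,
        "label": label,
        "freq": np.asarray(hdr["freq"], dtype=float),
        "time": np.asarray(hdr["time"], dtype=float),
        "trialinfo": np.asarray(hdr["trialinfo"], dtype=float),
        "dimord": "rpt_chan_freq_time",
    }
    savemat(mat_path, {"freq_data": struct})


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
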