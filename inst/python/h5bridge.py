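#!/usr/bin/env python
"""Raw-buffer <-> HDF5 bridge for the R package.

Modes:
  pack   manifest.json out.h5   -- write datasets described by the manifest
  unpack in.h5 manifest.json    -- dump datasets to raw buffers + manifest

Buffers are little-endian float64 / complex128 in Fortran (column-major)
order with R-side dims; HDF5 datasets use the fastMRI axis convention, i.e.
the reverse axis order (C order of the transposed array). Compound complex
dtypes with (r, i) or (re, im) fields are accepted on read.
"""
import json
import sys

import h5py
import numpy as np


def pack(manifest_path, out_path):
    with open(manifest_path) as fh:
        manifest = json.load(fh)
    with h5py.File(out_path, "w") as f:
        for ds in manifest["datasets"]:
            dtype = np.complex128 if ds["kind"] == "complex" else np.float64
            dims = [int(d) for d in ds["dims"]]
            a = np.fromfile(ds["bin"], dtype=dtype).reshape(dims, order="F")
            # file stores reversed axis order (e.g. slice, coil, row, col)
            f.create_dataset(ds["name"], data=a.transpose(range(a.ndim - 1, -1, -1)))
        attrs = manifest.get("attrs", {})
        if isinstance(attrs, list):  # empty named list serializes as []
            attrs = {}
        for k, v in attrs.items():
            f.attrs[k] = v


def _to_complex(a):
    if a.dtype.names:
        names = a.dtype.names
        if set(names) >= {"r", "i"}:
            return a["r"] + 1j * a["i"]
        if set(names) >= {"re", "im"}:
            return a["re"] + 1j * a["im"]
        raise ValueError(f"unrecognized compound dtype {a.dtype}")
    return a


def unpack(in_path, manifest_path):
    out = {"datasets": [], "attrs": {}}
    base = manifest_path[: -len(".json")] if manifest_path.endswith(".json") else manifest_path
    with h5py.File(in_path, "r") as f:
        names = []
        f.visit(lambda n: names.append(n) if isinstance(f[n], h5py.Dataset) else None)
        for i, name in enumerate(names):
            a = _to_complex(f[name][()])
            kind = "complex" if np.iscomplexobj(a) else "real"
            a = a.astype(np.complex128 if kind == "complex" else np.float64)
            # reverse axes back to R order, then dump column-major
            a = a.transpose(range(a.ndim - 1, -1, -1))
            bin_path = f"{base}_{i}.bin"
            a.flatten(order="F").tofile(bin_path)
            out["datasets"].append(
                {"name": name, "kind": kind, "dims": list(a.shape), "bin": bin_path}
            )
        for k, v in f.attrs.items():
            if isinstance(v, (np.generic, np.ndarray)):
                v = v.tolist()
            if isinstance(v, bytes):
                v = v.decode()
            out["attrs"][k] = v
    with open(manifest_path, "w") as fh:
        json.dump(out, fh)


def main(argv):
    if len(argv) != 4 or argv[1] not in {"pack", "unpack"}:
        sys.stderr.write(__doc__)
        return 2
    if argv[1] == "pack":
        pack(argv[2], argv[3])
    else:
        unpack(argv[2], argv[3])
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv))
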