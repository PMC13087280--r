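"""UMAP embedding backend: fit on the original feature vectors, transform
the synthetic ones into the same 2-D space.

Usage: python umap_embed.py <dir> <seed> <n_neighbors> <min_dist>
Reads <dir>/orig.csv and <dir>/syn.csv (no headers), writes
<dir>/emb_orig.csv and <dir>/emb_syn.csv.
"""
import sys

import numpy as np
import umap


def main():
    d, seed, n_neighbors, min_dist = (
        sys.argv[1], int(sys.argv[2]), int(sys.argv[3]), float(sys.argv[4]))
    orig = np.loadtxt(f"{d}/orig.csv", delimiter=",", ndmin=2)
    syn = np.loadtxt(f"{d}/syn.csv", delimiter=",", ndmin=2)
    reducer = umap.UMAP(n_components=2, n_neighbors=n_neighbors,
                        min_dist=min_dist, random_state=seed)
    emb_orig = reducer.fit_transform(orig)
    emb_syn = reducer.transform(syn)
    np.savetxt(f"{d}/emb_orig.csv", emb_orig, delimiter=",")
    np.savetxt(f"{d}/emb_syn.csv", emb_syn, delimiter=",")


if __name__ == "__main__":
    main()
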