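"""Penultimate fully-connected (fc7) AlexNet activations for coralbof.

Called by the R package's `alexnet-fc7` backend. Reads a CSV whose rows
are flattened resized patches (channels R,G,B concatenated, column-major
within each channel, values in [-0.5, 0.5]), runs them through pretrained
AlexNet up to the penultimate fully-connected layer, and writes the
activations as CSV. Requires torch + torchvision with downloadable (or
cached) pretrained weights; the R side refuses to construct the backend
when this stack is absent.

Usage: python alexnet_fc7.py <in.csv> <out.csv> <input_size>
"""
import sys

import numpy as np
import torch
import torchvision


def main(fin, fout, s):
    s = int(s)
    X = np.loadtxt(fin, delimiter=",", ndmin=2)
    n = X.shape[0]
    # column-major s x s per channel -> (n, 3, s, s) row-major tensors
    imgs = X.reshape(n, 3, s, s, order="F").transpose(0, 1, 3, 2)
    imgs = imgs + 0.5  # back to [0, 1]
    mean = np.array([0.485, 0.456, 0.406]).reshape(1, 3, 1, 1)
    std = np.array([0.229, 0.224, 0.225]).reshape(1, 3, 1, 1)
    imgs = (imgs - mean) / std
    model = torchvision.models.alexnet(weights="DEFAULT")
    model.eval()
    # fc7 = activations after the second Linear+ReLU of the classifier head
    feat = torch.nn.Sequential(
        model.features, model.avgpool, torch.nn.Flatten(),
        *list(model.classifier.children())[:-1]
    )
    with torch.no_grad():
        out = feat(torch.as_tensor(imgs, dtype=torch.float32)).numpy()
    np.savetxt(fout, out, delimiter=",")


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2], sys.argv[3])
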