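# Desk-scale configuration: small dimensions and a short schedule for
# CPU-only runs on synthetic or subsampled data.
L: 3
d_g: 64
d_t: 64
d_p: 64
N: 5
K: 5
epochs: 20
batch_size: 128
lr: 0.001
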