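# Published full-scale training configuration.
L: 3
d_g: 64
d_t: 64
d_p: 64
N: 5
K: 5
epochs: 100
batch_size: 128
lr: 0.00008
weight_decay: 0.0001
lambda_align: 0.9
lambda_pred: 0.9
lambda_proto: 0.9
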