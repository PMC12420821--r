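# Reference study conditions: 4-30-3 network on Yin-Yang, span 2 tau_s.
hidden: 30
delay_kind: none
lambda: 2
span: 2
tau_ratio: 2
delta_t: 0.2
lr_w: 0.02
lr_theta: 0.03
batch_size: 50
epochs: 300
n_train: 5000
n_val: 1000
n_test: 1000
seed: 1
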