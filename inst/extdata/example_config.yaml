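# Example configuration for the erspnet CLI (`--config` flag).
# Individual command-line flags override these values.
seed: 7
n_per_group: 6
frames: 24
alpha_db: -3
theta_db: 3
arch: cnn
epochs: 20
batch: 32
lr: 0.001
ipw: false
mode: task
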