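condition: normal
stripe_orientation: 0.0
filter_strength: 4.0
normal_fraction: 0.1
binocular_fraction: 0.0
boxcar_length: 150
noise_spec: ~
noise_fraction: 0.0
deprived_eye: right
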