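# No side-dependent modulation: left and right trials are statistically
# identical; decoding must sit at chance.
preset: null
seed: 1
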