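# Strong side-selective modulation: benchmark for kernel recovery and
# decoding. 8 CA3 inputs (6 modulated, gain x3, sd 125 ms bumps),
# 4 CA1 outputs, 200 trials.
preset: easy
seed: 1
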