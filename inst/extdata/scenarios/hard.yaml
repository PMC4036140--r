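# Weak modulation (gain x1.5 in 2 of 6 CA3 neurons), 100 trials.
preset: hard
seed: 1
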