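alpha_max: 1.0
fold: 100.0
hill_n: 1.0
K: 50.0
beta: 0.025
burst: 5
volume: 1.0
theta: 0.5
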