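{"tool":"autocircuit","version":"0.1.0","columns":["quantity","value"],"rows":3,"config":{"params":{"alpha_max":1,"fold":100,"hill_n":1,"K":1,"beta":1,"burst":1,"volume":1},"options":[]}}
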