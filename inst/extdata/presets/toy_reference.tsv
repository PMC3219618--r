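quantity	value
x_star_theta0	0.01
x_star_theta1	0.1
s_max_closed_form	5.5
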