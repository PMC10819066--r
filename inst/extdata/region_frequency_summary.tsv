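region	mean_th	sd_th	n_th	mean_me	sd_me	n_me
surface	0.0081	0.0202	20	0.0091	0.0280	20
boundary	0.7253	0.1546	20	0.8025	0.1203	20
core	0.2673	0.1573	20	0.1884	0.1099	20
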