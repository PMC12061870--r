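drug	shape	shape_lo	shape_hi	scale	scale_lo	scale_hi	type
adalimumab	0.69	0.65	0.72	428.94	390.07	467.82	early
golimumab	0.76	0.61	0.91	605.08	401.13	809.02	early
certolizumab pegol	0.79	0.69	0.89	423.69	331.58	515.80	early
etanercept	0.73	0.68	0.78	900.26	788.63	1011.89	early
infliximab	0.60	0.55	0.65	354.64	292.63	416.66	early
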