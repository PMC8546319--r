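variable	role	vtype	mean	dist_kind	dist_params	n
age	predictor	continuous	51.9699999999999989	gaussian	51.9699999999999989, 8.0252375061962518	1200
y1	phenotype	continuous	 1.9218558390334848	none		1200
y2	phenotype	continuous	 1.8703891835389919	none		1200
(Intercept)	intercept	continuous	 1.0000000000000000	degenerate	1	1200
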