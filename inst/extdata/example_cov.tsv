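	age	y1	y2	(Intercept)
age	64.404437030859043034	0.848066960683188986	-0.050700194358039706	0.000000000000000000
y1	0.848066960683188986	0.618564106179841255	0.368982122085058650	0.000000000000000000
y2	-0.050700194358039706	0.368982122085058650	1.147184785310049415	0.000000000000000000
(Intercept)	0.000000000000000000	0.000000000000000000	0.000000000000000000	0.000000000000000000
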