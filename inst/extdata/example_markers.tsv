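snp	maf	n	beta_y1	beta_y2
rs0001	0.1	1200	-0.0323164	0.0462432
rs0002	0.213	1200	0.124494	-0.00219406
rs0003	0.478	1200	0.00324693	-0.0199185
rs0004	0.49	1200	0.01125	0.0233254
rs0005	0.295	1200	0.0599175	-0.0599464
rs0006	0.28	1200	0.00852021	0.00517028
rs0007	0.225	1200	-0.0326497	-0.0645849
rs0008	0.168	1200	0.0457429	0.0440056
rs0009	0.318	1200	0.019112	0.056141
rs0010	0.266	1200	0.0138256	0.0143361
rs0011	0.457	1200	-0.0253889	-0.0257125
rs0012	0.132	1200	0.00866741	-0.07622
rs0013	0.34	1200	-0.00850648	-0.0648279
rs0014	0.385	1200	0.0580595	-0.0132554
rs0015	0.209	1200	0.0646287	-0.0208346
rs0016	0.115	1200	0.0199144	-0.0386852
rs0017	0.321	1200	0.000671349	-0.0926178
rs0018	0.362	1200	-0.0288616	-0.00706731
rs0019	0.2	1200	-0.0557901	-0.10865
rs0020	0.341	1200	-0.0421928	-0.0558914
rs0021	0.442	1200	-0.0364357	-0.00612599
rs0022	0.13	1200	0.0349559	-0.042654
rs0023	0.276	1200	0.0110427	0.0278743
rs0024	0.265	1200	-0.0398403	0.0258261
rs0025	0.496	1200	-0.0243406	0.0432191
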