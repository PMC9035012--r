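# GROMOS-compatible SASA implicit-solvation parameters, two sigma sets.
# radius_nm and p_i from the Hasel et al. parameterisation; sigma in kJ mol^-1 nm^-2.
# NA marks undefined entries; atoms of such types are excluded (radius NA) or
# raise on energy evaluation (sigma NA with radius defined) unless overridden.
# surface_class drives the hydrophilic/hydrophobic/total area bookkeeping.
code	name	radius_nm	p_i	sigma_per_type	sigma_three_class	class_three	surface_class	description
1	O	0.150	0.926	-7.2	-7.3	polar	hydrophilic	Carbonyl oxygen (C=O)
2	OM	0.170	0.922	-21.7	-23.3	charged	hydrophilic	Carboxyl oxygen (CO-)
3	OA	0.152	1.080	-7.0	-7.3	polar	hydrophilic	Hydroxyl or sugar oxygen
4	OE	0.152	1.080	NA	NA	NA	hydrophilic	Ether or ester oxygen
5	OW	NA	NA	NA	NA	NA	hydrophilic	Water oxygen
6	N	0.155	1.028	0.0	0.0	neutral	hydrophilic	Peptide nitrogen (NH)
7	NT	0.160	1.215	-4.0	-7.3	polar	hydrophilic	Terminal nitrogen (NH2)
8	NL	0.160	1.215	-26.1	-23.3	charged	hydrophilic	Terminal nitrogen (NH3)
9	NR	0.155	1.028	-4.5	-7.3	polar	hydrophilic	Aromatic nitrogen
10	NZ	0.155	1.028	-13.3	-23.3	charged	hydrophilic	Arg NH (NH2)
11	NE	0.155	1.028	0.0	0.0	neutral	hydrophilic	Arg NE (NH)
12	C	0.172	1.554	0.0	0.0	neutral	hydrophobic	Bare carbon
13	CH0	0.172	1.554	NA	NA	NA	hydrophobic	Bare sp3 carbon, 4 bound heavy atoms
14	CH1	0.180	1.276	3.8	4.1	hydrophobic	hydrophobic	Aliphatic or sugar CH-group
15	CH2	0.190	1.045	5.0	4.1	hydrophobic	hydrophobic	Aliphatic or sugar CH2-group
16	CH3	0.200	0.880	3.3	4.1	hydrophobic	hydrophobic	Aliphatic CH3-group
17	CH4	NA	NA	NA	NA	NA	hydrophobic	Methane
18	CH2r	0.190	1.045	NA	NA	NA	hydrophobic	Aliphatic or sugar CH2-group in ring
19	CR1	0.180	1.073	4.5	4.1	hydrophobic	hydrophobic	Aromatic CH-group
20	HC	0.110	1.128	0.0	0.0	NA	other	Hydrogen bound to carbon
21	H	0.110	1.128	0.0	0.0	NA	other	Hydrogen not bound to carbon
22	DUM	NA	NA	NA	NA	NA	other	Dummy atom
23	S	0.180	1.121	0.0	0.0	NA	other	Sulphur
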