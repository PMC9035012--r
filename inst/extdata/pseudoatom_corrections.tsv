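# NOE upper-bound corrections for pseudo-atom / multiplet representations, nm.
# Editable package data: applied when a restraint endpoint is a pseudo-site or a
# wildcard spanning equivalent protons. kind matches the resolved endpoint class.
kind	correction_nm	note
CH3	0.10	methyl pseudo-site at the carbon
CH2_wildcard	0.10	unresolved prochiral methylene pair
ring_wildcard	0.20	aromatic ring HD*/HE* pair
double_CH3	0.20	two equivalent methyls (e.g. Leu HD*, Val HG*)
none	0.00	stereospecifically resolved proton
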