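# Ideal internal coordinates used by the synthetic toy-chain generator.
# Lengths in nm, angles in degrees. Only self-consistency matters: generated
# bond lengths must equal the constraint targets exactly.
parameter	value	unit
bond_N_CA	0.147	nm
bond_CA_C	0.153	nm
bond_C_N	0.133	nm
bond_C_O	0.123	nm
bond_CA_CB	0.153	nm
angle_N_CA_C	111.0	deg
angle_CA_C_N	117.0	deg
angle_C_N_CA	122.0	deg
angle_CA_C_O	121.0	deg
angle_backbone_CB	110.0	deg
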