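# Bundled mini catalog of well-known medicinal-chemistry structural-alert
# SMARTS patterns (a small subset of the widely used public alert sets; the
# source column tags the catalog family each pattern is associated with).
# Columns: name<TAB>smarts<TAB>source
nitro_group	[N+](=O)[O-]	Glaxo
aliphatic_aldehyde	[CX3H1]=O	Dundee
acyl_halide	C(=O)[F,Cl,Br,I]	Glaxo
epoxide	C1OC1	Glaxo
azo_group	N=N	Dundee
isocyanate	N=C=O	Glaxo
thiol	[SX2H]	Dundee
peroxide	[OX2][OX2]	Glaxo
hydrazine	[NX3][NX3]	Dundee
alkyl_halide	[CX4][Cl,Br,I]	Dundee
michael_acceptor	[CX3]=[CX3][CX3]=[OX1]	Dundee
acyclic_imine	[CX3;!R]=[NX2;!R]	Dundee
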