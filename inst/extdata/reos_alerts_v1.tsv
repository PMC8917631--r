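# Functional-group reactivity alerts in the spirit of the REOS scheme
# (Walters & Murcko 2002): substructure rules flagging reactive, unstable or
# assay-hostile groups. Substructure alerts only; property-range rules are
# out of scope. version: 1
acyl_halide	[Cl,Br,I][CX3]=[OX1]
sulfonyl_halide	[Cl,Br,I][SX4](=[OX1])=[OX1]
alkyl_halide	[Cl,Br,I][CX4]
aldehyde	[CX3H1]=[OX1]
epoxide_aziridine	[CX4]1[OX2,NX3][CX4]1
anhydride	[CX3](=[OX1])[OX2][CX3]=[OX1]
peroxide	[OX2][OX2]
azide	[NX2]=[NX2+]=[NX1-,NX2]
diazonium	[NX2+]#[NX1]
isocyanate	[NX2]=[CX2]=[OX1,SX1]
michael_acceptor	[CX3]=[CX3][CX3]=[OX1]
nitro	[NX3+](=[OX1])[OX1-]
thiol	[SX2H]
hydrazine	[NX3H2][NX3H2,NX3H1]
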