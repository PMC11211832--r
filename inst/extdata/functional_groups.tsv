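name	smarts
hydroxyl	[OX2H]
primary_alcohol	[CX4H2][OX2H]
secondary_alcohol	[CX4H1]([#6])[OX2H]
tertiary_alcohol	[CX4]([#6])([#6])([#6])[OX2H]
phenol	c[OX2H]
ether	[OD2]([#6])[#6]
aromatic_ether	[OD2](c)[#6]
methoxy	[OX2][CH3]
peroxide	[OX2][OX2]
aldehyde	[CX3H1]=[OX1]
ketone	[#6][CX3](=[OX1])[#6]
carbonyl	[CX3]=[OX1]
carboxylic_acid	[CX3](=[OX1])[OX2H1]
carboxylate	[CX3](=[OX1])[OX1-]
ester	[CX3](=[OX1])[OX2][#6]
lactone	[C;R](=[OX1])[O;R]
anhydride	[CX3](=[OX1])[OX2][CX3]=[OX1]
carbonate	[OX2][CX3](=[OX1])[OX2]
amide	[NX3][CX3]=[OX1]
primary_amide	[NX3H2][CX3]=[OX1]
secondary_amide	[NX3H1]([#6])[CX3]=[OX1]
tertiary_amide	[NX3]([#6])([#6])[CX3]=[OX1]
lactam	[N;R][C;R]=[OX1]
carbamate	[NX3][CX3](=[OX1])[OX2]
urea	[NX3][CX3](=[OX1])[NX3]
thiourea	[NX3][CX3](=[SX1])[NX3]
guanidine	[NX3][CX3]=[NX2]
primary_amine	[NX3H2][#6]
secondary_amine	[NX3H1]([#6])[#6]
tertiary_amine	[NX3H0]([#6])([#6])[#6]
quaternary_ammonium	[NX4+]
aromatic_amine	c[NX3]
aromatic_nitrogen	[n]
nitrile	[NX1]#[CX2]
isocyanate	[NX2]=[CX2]=[OX1]
isothiocyanate	[NX2]=[CX2]=[SX1]
nitro	[NX3+](=[OX1])[OX1-]
nitroso	[NX2]=[OX1]
n_oxide	[#7+][OX1-]
azo	[NX2]=[NX2]
azide	[NX2]=[NX2+]=[NX1-]
hydrazine	[NX3][NX3]
hydrazone	[NX3][NX2]=[CX3]
imine	[CX3]=[NX2]
oxime	[CX3]=[NX2][OX2H]
thiol	[SX2H]
sulfide	[SX2]([#6])[#6]
disulfide	[SX2][SX2]
sulfoxide	[SX3]=[OX1]
sulfone	[SX4](=[OX1])=[OX1]
sulfonamide	[SX4](=[OX1])(=[OX1])[NX3]
sulfonic_acid	[SX4](=[OX1])(=[OX1])[OX2H]
thiocarbonyl	[CX3]=[SX1]
aromatic_sulfur	[s]
fluoro	[F]
chloro	[Cl]
bromo	[Br]
iodo	[I]
trifluoromethyl	[CX4](F)(F)F
acyl_halide	[CX3](=[OX1])[F,Cl,Br,I]
haloalkane	[CX4][F,Cl,Br,I]
haloarene	c[F,Cl,Br,I]
alkene	[CX3]=[CX3]
alkyne	[CX2]#[CX2]
conjugated_diene	[CX3]=[CX3][CX3]=[CX3]
aromatic_ring	[a]
benzene_ring	c1ccccc1
heteroaromatic	[a;!c]
pyridine_ring	n1ccccc1
pyrrole_ring	[nH]1cccc1
furan_ring	o1cccc1
thiophene_ring	s1cccc1
imidazole_ring	[nH]1cncc1
pyrazole_ring	[nH]1nccc1
oxazole_ring	o1cncc1
thiazole_ring	s1cncc1
tetrazole_ring	[nH]1nnnc1
fused_aromatic	c1ccc2ccccc2c1
aliphatic_ring	[C;R]
aliphatic_n_heterocycle	[NX3;R]
piperazine_ring	[NX3;R]1CC[NX3;R]CC1
morpholine_ring	[OX2;R]1CC[NX3;R]CC1
epoxide	[OX2r3]
small_ring	[r3,r4]
large_ring	[r7,r8]
phosphoryl	[PX4]=[OX1]
boron	[B]
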