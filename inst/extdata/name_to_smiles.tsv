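name	smiles
water	O
methanol	CO
ethanol	CCO
isopropanol	CC(C)O
2-propanol	CC(C)O
acetone	CC(C)=O
acetonitrile	CC#N
tetrahydrofuran	C1CCOC1
thf	C1CCOC1
dichloromethane	ClCCl
dcm	ClCCl
chloroform	ClC(Cl)Cl
1,2-dichloroethane	ClCCCl
toluene	Cc1ccccc1
benzene	c1ccccc1
hexane	CCCCCC
n-hexane	CCCCCC
pentane	CCCCC
cyclohexane	C1CCCCC1
diethyl ether	CCOCC
ether	CCOCC
ethyl acetate	CCOC(C)=O
n,n-dimethylformamide	CN(C)C=O
dimethylformamide	CN(C)C=O
dmf	CN(C)C=O
dimethyl sulfoxide	CS(C)=O
dmso	CS(C)=O
1,4-dioxane	C1COCCO1
dioxane	C1COCCO1
n-methyl-2-pyrrolidone	CN1CCCC1=O
nmp	CN1CCCC1=O
ethylene glycol	OCCO
glycerol	OCC(O)CO
1-propanol	CCCO
tert-butyl methyl ether	COC(C)(C)C
1,2-dimethoxyethane	COCCOC
dme	COCCOC
sodium hydroxide	[Na+].[OH-]
potassium hydroxide	[K+].[OH-]
sodium carbonate	O=C([O-])[O-].[Na+].[Na+]
sodium carbonate monohydrate	O=C([O-])[O-].[Na+].[Na+]
sodium carbonate decahydrate	O=C([O-])[O-].[Na+].[Na+]
potassium carbonate	O=C([O-])[O-].[K+].[K+]
potassium carbonate sesquihydrate	O=C([O-])[O-].[K+].[K+]
sodium borohydride	[Na+].[BH4-]
lithium aluminium hydride	[Li+].[AlH4-]
lithium aluminum hydride	[Li+].[AlH4-]
hydrogen	[H][H]
hydrochloric acid	Cl
sulfuric acid	OS(=O)(=O)O
nitric acid	ON(=O)=O
acetic acid	CC(=O)O
trifluoroacetic acid	OC(=O)C(F)(F)F
acetyl chloride	CC(=O)Cl
acetic anhydride	CC(=O)OC(C)=O
oxalyl chloride	ClC(=O)C(=O)Cl
triethylamine	CCN(CC)CC
pyridine	c1ccncc1
sodium acetate	CC(=O)[O-].[Na+]
sodium acetate trihydrate	CC(=O)[O-].[Na+]
potassium acetate	CC(=O)[O-].[K+]
sodium chloride	[Na+].[Cl-]
sodium iodide	[Na+].[I-]
potassium iodide	[K+].[I-]
bromine	BrBr
chlorine	ClCl
iodine	II
hydrazine	NN
hydrazine hydrate	NN
sodium methoxide	CO[Na]
sodium ethoxide	CC[O-].[Na+]
magnesium	[Mg]
zinc	[Zn]
iron	[Fe]
nickel	[Ni]
palladium	[Pd]
palladium chloride	Cl[Pd]Cl
platinum	[Pt]
thionyl chloride	O=S(Cl)Cl
methanesulfonyl chloride	CS(=O)(=O)Cl
p-toluenesulfonic acid	Cc1ccc(cc1)S(=O)(=O)O
p-toluenesulfonic acid monohydrate	Cc1ccc(cc1)S(=O)(=O)O
hydrogen peroxide	OO
triphenylphosphine	c1ccc(cc1)P(c1ccccc1)c1ccccc1
sodium azide	[Na+].[N-]=[N+]=[N-]
potassium tert-butoxide	CC(C)(C)[O-].[K+]
boric acid	B(O)O
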