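group	n_terms	n_genes	genes
Muscle	2	1	MYBPC3
ECM/Collagen	6	8	COL6A3,SERPINA1,TNXB,FLRT2,DST,COL5A2,COL6A5,TINAG
Microtubule Cytoskeleton	6	12	DNAH8,DNAH6,DNHD1,DST,KIF15,MACF1,SULT1C2,C2CD3,AKAP9,MCM3,NPHP4,CEP290
Cilium	4	5	PCDH15,C2CD3,CEP290,DNAH8,NPHP4
Stereocilium	3	4	LOXHD1,PCDH15,USH1C,LRP2
Neuron/Synapse	7	15	EPS8,CPEB1,DLG1,GRID2,SEMA4C,EPHA7,LRRK2,SEMA3A,CHAT,PCDH15,USH1C,ARID1A,LOXHD1,SACS,CEP290
Plasma Membrane	4	31	EPHB6,SELPLG,CSF3R,NPY4R,LRP2,AQP2,ATP12A,EPS8,SLC22A14,GNGT2,FLRT2,STAB1,PCDHA4,EPHA7,GRID2,ABCC1,DST,MGA,SEMA4C,TNFRSF10C,PCDHA11,ATRN,CPEB1,PTPRB,DLG1,GJB4,CCKBR,NEDD4,SCNN1A,SLC26A7,FGFR1
Mitochondrial Membrane	1	1	LRRK2
Nucleus	2	1	MLH1
Unclustered Significant Terms	3	47	HIST1H2BJ,CHD9,NOP2,CHD6,NAT10,ZNF22,RRBP1,PPM1E,AKAP12,ORC4,MRPL3,CLSPN,LRRFIP1,FARP1,DDX11,KRT2,ELMOD3,DDX54,EBNA1BP2,TADA2A,TSR1,VCL,ECE2,GOLGA2,JPH3,GALNT8,TET1,CDC25A,ERN2,NDUFS8,MMRN1,MED20,PPIE,UQCRC2,GOLGA8A,POM121,SLC25A27,ATXN3,MAN2A2,UBN1,DHX38,SSR1,ATRIP,B3GAT2,DNAJC11,SON,QARS
Not Annotated	NA	49	FASTKD1,ULK4,DDX60L,FAM216A,C16ORF71,C6ORF223,EVA1A,HENMT1,EPG5,IAH1,C21ORF58,TET2,RNF208,JOSD2,KIF7,PALD1,ATAD3C,PATL2,FCHSD1,THAP3,POM121L2,KIAA1257,CCDC42B,METTL20,DXO,NUTM2G,TRABD2A,TRUB1,TRIM51,STAMBPL1,DCDC2B,BCO1,C16ORF52,FAM83C,LEKR1,HELQ,FBXO39,TYW1B,DNAJC13,FAM111B,BPIFB1,NOL4L,ST5,KANSL3,R3HCC1,GNB3,CEP162,KBTBD8,CCDC173
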