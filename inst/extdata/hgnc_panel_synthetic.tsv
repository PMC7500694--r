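symbol	name	alias_symbol	prev_symbol	alias_name
XIST	X inactive specific transcript	LINC00001|SXI1
RPS4Y1	ribosomal protein S4 Y-linked 1	RPS4Y		ribosomal protein S4 Y isoform
RPS4Y2	ribosomal protein S4 Y-linked 2	RPS4Y2P
KDM5D	lysine demethylase 5D	JARID1D|HYA	SMCY
DDX3Y	DEAD-box helicase 3 Y-linked	DBY
UTY	ubiquitously transcribed tetratricopeptide repeat containing Y-linked	UTY1|KDM6C
USP9Y	ubiquitin specific peptidase 9 Y-linked	DFFRY
EIF1AY	eukaryotic translation initiation factor 1A Y-linked
NLGN4Y	neuroligin 4 Y-linked	HNL4Y
TXLNGY	taxilin gamma pseudogene Y-linked	CYorf15A|MGC9999	CYORF15	taxilin gamma Y-linked
ZFY	zinc finger protein Y-linked
PRKY	protein kinase Y-linked pseudogene	PRKY1|PRKYP|MGC9999		Y-linked protein kinase pseudogene
TMSB4Y	thymosin beta 4 Y-linked
KDM6A	lysine demethylase 6A	bA386N14.2	UTX
ZFX	zinc finger protein X-linked
DDX3X	DEAD-box helicase 3 X-linked	DBX|HLP2
EIF1AX	eukaryotic translation initiation factor 1A X-linked	EIF1A
DPP4	dipeptidyl peptidase 4	CD26|ADCP2|ADABP		adenosine deaminase complexing protein 2
FCGR1A	Fc gamma receptor Ia	CD64|FCRI		high affinity immunoglobulin gamma Fc receptor I
SOCS3	suppressor of cytokine signaling 3	CIS3|SSI3|Cish3
CD40LG	CD40 ligand	CD154|TRAP|gp39	TNFSF5
CXCR3	C-X-C motif chemokine receptor 3	GPR9|CD183|CKR-L2
IL2RG	interleukin 2 receptor subunit gamma	CD132|SCIDX1		common cytokine receptor gamma chain
TLR7	toll like receptor 7	TLR7-like
CCL5	C-C motif chemokine ligand 5	RANTES|SCYA5		regulated upon activation normally T-expressed
GZMB	granzyme B	CTLA1|CGL1|CSPB		cytotoxic T-lymphocyte-associated serine esterase 1
CAMP	cathelicidin antimicrobial peptide	CAP18|LL37|FALL39		LL-37 precursor peptide
CD99	CD99 molecule	MIC2	MIC2X
IFI44L	interferon induced protein 44 like	GS3686|C1orf29
MX1	MX dynamin like GTPase 1	MXA|IFI78	MX
OAS1	2'-5'-oligoadenylate synthetase 1	OIAS|IFI-4
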