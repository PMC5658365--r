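bgsc_id	name	role	ecoli_marker_digit	ori_digit	cargo_digit	bsu_marker_letter	descriptor	mcs_iis	description
ECE701	pBSd141R	destination	1	4	1		R	F2,B1	mRFP1 stuffer, bla, ori pRO1600/ColE1 (high copy)
ECE702	pBSd191R	destination	1	9	1		R	F2,B1	mRFP1 stuffer, bla, ori pBR322/ROP (medium copy)
ECE703	pSEVA243X	storage_up	2	4	3		X	B2,C1	lacZalpha**-pUC18 MCS with MCS-IIS B2+C1 for up fragments, neo, ori pRO1600/ColE1
ECE704	pSEVA243Y	storage_down	2	4	3		Y	E2,F1	lacZalpha**-pUC18 MCS with MCS-IIS E2+F1 for down fragments, neo, ori pRO1600/ColE1
ECE706	pBSc241B	cargo_resistance	2	4	1	B		E1,C2	default MCS, bleO, ori pRO1600/ColE1
ECE707	pBSc241C	cargo_resistance	2	4	1	C		E1,C2	default MCS, cat, ori pRO1600/ColE1
ECE708	pBSc241M	cargo_resistance	2	4	1	M		E1,C2	default MCS, ermC, ori pRO1600/ColE1
ECE709	pBSc241S	cargo_resistance	2	4	1	S		E1,C2	default MCS, aad(9), ori pRO1600/ColE1
ECE710	pBSc241T	cargo_resistance	2	4	1	T		E1,C2	default MCS, tetL, ori pRO1600/ColE1
ECE711	pBSc241Z	cargo_resistance	2	4	1	Z		E1,C2	default MCS, ble-Sh, ori pRO1600/ColE1
ECE720	pBSc291K	cargo_resistance	2	9	1	K		E1,C2	default MCS, aph(3')IIIa, ori pBR322/ROP
ECE713	pBSc243B	cargo_resistance	2	4	3	B		E1,C2	lacZalpha*-pUC18 MCS, bleO, ori pRO1600/ColE1
ECE714	pBSc243C	cargo_resistance	2	4	3	C		E1,C2	lacZalpha*-pUC18 MCS, cat, ori pRO1600/ColE1
ECE715	pBSc243M	cargo_resistance	2	4	3	M		E1,C2	lacZalpha*-pUC18 MCS, ermC, ori pRO1600/ColE1
ECE716	pBSc243S	cargo_resistance	2	4	3	S		E1,C2	lacZalpha*-pUC18 MCS, aad(9), ori pRO1600/ColE1
ECE717	pBSc243T	cargo_resistance	2	4	3	T		E1,C2	lacZalpha*-pUC18 MCS, tetL, ori pRO1600/ColE1
ECE718	pBSc243Z	cargo_resistance	2	4	3	Z		E1,C2	lacZalpha*-pUC18 MCS, ble-Sh, ori pRO1600/ColE1
ECE721	pBSc293K	cargo_resistance	2	9	3	K		E1,C2	lacZalpha*-pUC18 MCS, aph(3')IIIa, ori pBR322/ROP
ECE705	pBSc241	markerless_cargo	2	4	1			E1,C2	default MCS, no Bacillus marker, ori pRO1600/ColE1
ECE712	pBSc243	markerless_cargo	2	4	3			E1,C2	lacZalpha*-pUC18 MCS, no Bacillus marker, ori pRO1600/ColE1
ECE719	pBSc291	markerless_cargo	2	9	1			E1,C2	default MCS, no Bacillus marker, ori pBR322/ROP
ECE725	pBSc293	markerless_cargo	2	9	3			E1,C2	lacZalpha*-pUC18 MCS, no Bacillus marker, ori pBR322/ROP
ECE722	pBSc391	markerless_cargo	3	9	1			E1,C2	default MCS, no Bacillus marker, cat, ori pBR322/ROP
ECE726	pBSc393	markerless_cargo	3	9	3			E1,C2	lacZalpha*-pUC18 MCS, no Bacillus marker, cat, ori pBR322/ROP
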