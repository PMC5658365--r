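junction	overhang	mcs_ids	canonical
B	CCAT	B1/B2	FALSE
C	GCGA	C1/C2	TRUE
E	TGAC	E1/E2	FALSE
F	GTTC	F1/F2	FALSE
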