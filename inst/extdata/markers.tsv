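letter	gene	description	antibiotic	concentration_ug_ml
B	bleO	bleomycin binding protein (phleomycin D)	phleomycin D1	100
C	cat	chloramphenicol O-acetyltransferase	chloramphenicol	5
K	aph(3')IIIa	aminoglycoside O-phosphotransferase APH(3')-IIIa	kanamycin	10
M	ermC	23S rRNA (adenine(2058)-N(6))-methyltransferase	erythromycin & lincomycin	1 & 25
S	aad(9)	aminoglycoside nucleotidyltransferase ANT9	spectinomycin	200
T	tetL	tetracycline efflux MFS transporter	tetracycline	12.5
Z	ble-Sh	phleomycin/bleomycin binding protein (Bsu codon-optimized)	zeocin	100
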