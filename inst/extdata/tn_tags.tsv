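label	tag_sequence	gene
DK6008	TATGCAAGGA	rocD
DK6012	TATTTGAGGA	divIVA
DK6013	TATGCCCAAC	ahpC
DK6035	TAGAACCTGA	ybbC
DK6832	TAGACAAGCT	motA
DK6833	TAGACAAGCT	motA
DK7191	TAGATGATGT	ezrA
DK7196	TACATGATGA	msmX
DK7197	TAGCATGGAG	glnA
DK8062	TATTTGAGGA	divIVA
DK8179	TAGCATGGAG	glnA
DK8247	TATGCCCAAC	ahpC
DK8248	TAGAACCTGA	ybbC
DK8249	TACATGATGA	msmX
DK8439	TAGGCGCATT	ftsZ_372
DK8440	TAGAGTATAT	ftsZ_114
DK8441	TAGGAGGCGG	ftsZ_57
DK8442	TAAATCAAAG	ftsZ_990
DK8443	TAAAGGTGCT	ftsZ_280
DK8444	TAGAGGATTG	ftsZ_199
DK8445	TAGAATGTTG	ftsZ_m4
DK8478	TAGATGATGT	ezrA
DK8479	TATGCAAGGA	rocD
DK8580	TATTGATGTT	citB
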