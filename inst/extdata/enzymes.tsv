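name	recognition	cut_offset
AluI	AGCT	2
BamHI	GGATCC	1
BanI	GGYRCC	1
BstEII	GGTNACC	1
DpnII	GATC	0
DraI	TTTAAA	3
EcoRI	GAATTC	1
EcoRV	GATATC	3
HaeIII	GGCC	2
HindIII	AAGCTT	1
HinfI	GANTC	1
KpnI	GGTACC	5
MluI	ACGCGT	1
MseI	TTAA	1
MspI	CCGG	1
NcoI	CCATGG	1
NdeI	CATATG	2
PstI	CTGCAG	5
RsaI	GTAC	2
ScrFI	CCNGG	2
SmaI	CCCGGG	3
SpeI	ACTAGT	1
SspI	AATATT	3
StyI	CCWWGG	1
TaqI	TCGA	1
XbaI	TCTAGA	1
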