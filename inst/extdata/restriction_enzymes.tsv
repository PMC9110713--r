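name	site	cut_top	cut_bottom
EcoRI	GAATTC	1	5
BamHI	GGATCC	1	5
HindIII	AAGCTT	1	5
NdeI	CATATG	2	4
XhoI	CTCGAG	1	5
SalI	GTCGAC	1	5
XbaI	TCTAGA	1	5
PstI	CTGCAG	5	1
SphI	GCATGC	5	1
KpnI	GGTACC	5	1
SacI	GAGCTC	5	1
SmaI	CCCGGG	3	3
EcoRV	GATATC	3	3
HpaI	GTTAAC	3	3
PvuII	CAGCTG	3	3
StuI	AGGCCT	3	3
ScaI	AGTACT	3	3
NruI	TCGCGA	3	3
NcoI	CCATGG	1	5
NheI	GCTAGC	1	5
SpeI	ACTAGT	1	5
AvrII	CCTAGG	1	5
BglII	AGATCT	1	5
MluI	ACGCGT	1	5
ApaI	GGGCCC	5	1
AflII	CTTAAG	1	5
AgeI	ACCGGT	1	5
BspEI	TCCGGA	1	5
NotI	GCGGCCGC	2	6
AscI	GGCGCGCC	2	6
PacI	TTAATTAA	5	3
PmeI	GTTTAAAC	4	4
SbfI	CCTGCAGG	6	2
FseI	GGCCGGCC	6	2
SwaI	ATTTAAAT	4	4
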