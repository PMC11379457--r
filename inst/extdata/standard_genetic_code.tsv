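codon	family	n_a
AAA	Lys	2
AAC	Asn	2
AAG	Lys	2
AAT	Asn	2
ACA	Thr	4
ACC	Thr	4
ACG	Thr	4
ACT	Thr	4
AGA	Arg	6
AGC	Ser	6
AGG	Arg	6
AGT	Ser	6
ATA	Ile	3
ATC	Ile	3
ATG	Met	1
ATT	Ile	3
CAA	Gln	2
CAC	His	2
CAG	Gln	2
CAT	His	2
CCA	Pro	4
CCC	Pro	4
CCG	Pro	4
CCT	Pro	4
CGA	Arg	6
CGC	Arg	6
CGG	Arg	6
CGT	Arg	6
CTA	Leu	6
CTC	Leu	6
CTG	Leu	6
CTT	Leu	6
GAA	Glu	2
GAC	Asp	2
GAG	Glu	2
GAT	Asp	2
GCA	Ala	4
GCC	Ala	4
GCG	Ala	4
GCT	Ala	4
GGA	Gly	4
GGC	Gly	4
GGG	Gly	4
GGT	Gly	4
GTA	Val	4
GTC	Val	4
GTG	Val	4
GTT	Val	4
TAA	STOP	3
TAC	Tyr	2
TAG	STOP	3
TAT	Tyr	2
TCA	Ser	6
TCC	Ser	6
TCG	Ser	6
TCT	Ser	6
TGA	STOP	3
TGC	Cys	2
TGG	Trp	1
TGT	Cys	2
TTA	Leu	6
TTC	Phe	2
TTG	Leu	6
TTT	Phe	2
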