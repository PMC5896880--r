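codon	weight
GCA	0.55
GCG	0.33
GCC	0.32
GCT	0.21
TGC	0.20
TGT	0.02
GAC	0.78
GAT	0.45
GAG	0.81
GAA	0.32
TTC	0.58
TTT	0.15
GGA	1.00
GGG	0.58
GGC	0.52
GGT	0.18
CAC	0.68
CAT	0.17
ATT	1.00
ATC	0.82
ATA	0.52
AAG	1.00
AAA	0.72
CTC	0.55
TTG	0.19
CTG	0.15
CTT	0.14
CTA	0.12
TTA	0.09
ATG	1.00
AAC	1.00
AAT	0.55
CCC	0.82
CCA	0.61
CCG	0.34
CCT	0.26
CAA	0.93
CAG	0.51
CGC	0.63
AGA	0.50
CGT	0.22
CGA	0.17
CGG	0.08
AGG	0.06
AGC	0.19
TCA	0.18
TCC	0.16
TCG	0.15
TCT	0.13
AGT	0.04
ACG	1.00
ACC	0.93
ACA	0.78
ACT	0.66
GTG	0.25
GTT	0.15
GTC	0.13
GTA	0.12
TGG	0.22
TAC	1.00
TAT	0.24
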