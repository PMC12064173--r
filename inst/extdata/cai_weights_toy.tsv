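UUU	0.7
UUC	1
UUA	0.38
UUG	0.33
UCU	0.33
UCC	0.45
UCA	0.55
UCG	0.38
UAU	0.7
UAC	1
UGU	0.7
UGC	1
UGG	1
CUU	0.45
CUC	0.7
CUA	1
CUG	0.55
CCU	0.45
CCC	0.7
CCA	1
CCG	0.55
CAU	0.7
CAC	1
CAA	1
CAG	0.7
CGU	0.33
CGC	0.45
CGA	0.55
CGG	0.38
AUU	0.55
AUC	0.7
AUA	1
AUG	1
ACU	0.45
ACC	0.7
ACA	1
ACG	0.55
AAU	0.7
AAC	1
AAA	1
AAG	0.7
AGU	0.7
AGC	1
AGA	1
AGG	0.7
GUU	0.45
GUC	0.7
GUA	1
GUG	0.55
GCU	0.45
GCC	0.7
GCA	1
GCG	0.55
GAU	0.7
GAC	1
GAA	1
GAG	0.7
GGU	0.45
GGC	0.7
GGA	1
GGG	0.55
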