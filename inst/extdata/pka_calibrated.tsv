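# ionization pKa values; NTERM/CTERM are the chain termini
NTERM	9
CTERM	3.1
D	3.65
E	4.25
C	8.14
Y	10.07
H	6
K	11.1
R	12.5
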