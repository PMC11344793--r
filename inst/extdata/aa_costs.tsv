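amino_acid	cost
Ala	11.7
Arg	27.3
Asn	14.7
Asp	12.7
Cys	24.7
Gln	16.3
Glu	15.3
Gly	11.7
His	38.3
Ile	32.3
Leu	27.3
Lys	30.3
Met	34.3
Phe	52.0
Pro	20.3
Ser	11.7
Thr	18.7
Trp	74.3
Tyr	50.0
Val	23.3
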