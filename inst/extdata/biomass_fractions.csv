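condition,protein,rna,lipid,phb,other
0,0.55,0.16,0.09,0.06,0.14
0.6,0.52,0.14,0.09,0.144,0.106
1.2,0.47,0.11,0.08,0.295,0.045
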