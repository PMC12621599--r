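MEME version 4

ALPHABET= ACGT

Background letter frequencies
A 0.300000 C 0.200000 G 0.200000 T 0.300000

MOTIF CPE
letter-probability matrix: alength= 4 w= 6
0.040000 0.040000 0.040000 0.880000
0.040000 0.040000 0.040000 0.880000
0.040000 0.040000 0.040000 0.880000
0.040000 0.040000 0.040000 0.880000
0.880000 0.040000 0.040000 0.040000
0.040000 0.040000 0.040000 0.880000

MOTIF PAS_HEXAMER
letter-probability matrix: alength= 4 w= 6
0.910000 0.030000 0.030000 0.030000
0.910000 0.030000 0.030000 0.030000
0.030000 0.030000 0.030000 0.910000
0.910000 0.030000 0.030000 0.030000
0.910000 0.030000 0.030000 0.030000
0.910000 0.030000 0.030000 0.030000
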