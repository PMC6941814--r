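MEME version 4

ALPHABET= ACGT

strands: + -

Background letter frequencies
A 0.25 C 0.25 G 0.25 T 0.25

MOTIF Arid3
letter-probability matrix: alength= 4 w= 6 nsites= 100 E= 0
0.850000 0.050000 0.050000 0.050000
0.950000 0.016667 0.016667 0.016667
0.016667 0.016667 0.016667 0.950000
0.016667 0.016667 0.016667 0.950000
0.950000 0.016667 0.016667 0.016667
0.850000 0.050000 0.050000 0.050000

MOTIF CEBPB
letter-probability matrix: alength= 4 w= 11 nsites= 100 E= 0
0.550000 0.150000 0.150000 0.150000
0.050000 0.050000 0.050000 0.850000
0.016667 0.016667 0.016667 0.950000
0.016667 0.016667 0.950000 0.016667
0.016667 0.950000 0.016667 0.016667
0.016667 0.016667 0.950000 0.016667
0.016667 0.950000 0.016667 0.016667
0.950000 0.016667 0.016667 0.016667
0.950000 0.016667 0.016667 0.016667
0.050000 0.050000 0.050000 0.850000
0.150000 0.550000 0.150000 0.150000

MOTIF FOSL1
letter-probability matrix: alength= 4 w= 11 nsites= 100 E= 0
0.550000 0.150000 0.150000 0.150000
0.050000 0.050000 0.050000 0.850000
0.016667 0.016667 0.950000 0.016667
0.950000 0.016667 0.016667 0.016667
0.050000 0.450000 0.450000 0.050000
0.016667 0.016667 0.016667 0.950000
0.016667 0.950000 0.016667 0.016667
0.950000 0.016667 0.016667 0.016667
0.016667 0.016667 0.016667 0.950000
0.050000 0.850000 0.050000 0.050000
0.550000 0.150000 0.150000 0.150000

MOTIF Gabpa
letter-probability matrix: alength= 4 w= 11 nsites= 100 E= 0
0.550000 0.150000 0.150000 0.150000
0.050000 0.850000 0.050000 0.050000
0.016667 0.950000 0.016667 0.016667
0.016667 0.016667 0.950000 0.016667
0.016667 0.016667 0.950000 0.016667
0.950000 0.016667 0.016667 0.016667
0.950000 0.016667 0.016667 0.016667
0.016667 0.016667 0.950000 0.016667
0.016667 0.016667 0.016667 0.950000
0.050000 0.050000 0.850000 0.050000
0.150000 0.150000 0.550000 0.150000

MOTIF MEF2A
letter-probability matrix: alength= 4 w= 15 nsites= 100 E= 0
0.150000 0.150000 0.150000 0.550000
0.150000 0.150000 0.550000 0.150000
0.050000 0.850000 0.050000 0.050000
0.016667 0.016667 0.016667 0.950000
0.950000 0.016667 0.016667 0.016667
0.016667 0.016667 0.016667 0.950000
0.016667 0.016667 0.016667 0.950000
0.016667 0.016667 0.016667 0.950000
0.016667 0.016667 0.016667 0.950000
0.016667 0.016667 0.016667 0.950000
0.950000 0.016667 0.016667 0.016667
0.016667 0.016667 0.950000 0.016667
0.050000 0.850000 0.050000 0.050000
0.550000 0.150000 0.150000 0.150000
0.150000 0.150000 0.550000 0.150000

MOTIF MAFK
letter-probability matrix: alength= 4 w= 15 nsites= 100 E= 0
0.150000 0.150000 0.550000 0.150000
0.150000 0.150000 0.150000 0.550000
0.050000 0.050000 0.850000 0.050000
0.016667 0.950000 0.016667 0.016667
0.016667 0.016667 0.016667 0.950000
0.016667 0.016667 0.950000 0.016667
0.950000 0.016667 0.016667 0.016667
0.016667 0.950000 0.016667 0.016667
0.016667 0.016667 0.016667 0.950000
0.016667 0.950000 0.016667 0.016667
0.950000 0.016667 0.016667 0.016667
0.016667 0.016667 0.950000 0.016667
0.050000 0.850000 0.050000 0.050000
0.550000 0.150000 0.150000 0.150000
0.150000 0.150000 0.550000 0.150000

MOTIF MAX
letter-probability matrix: alength= 4 w= 10 nsites= 100 E= 0
0.150000 0.150000 0.550000 0.150000
0.050000 0.050000 0.850000 0.050000
0.016667 0.950000 0.016667 0.016667
0.950000 0.016667 0.016667 0.016667
0.016667 0.950000 0.016667 0.016667
0.016667 0.016667 0.950000 0.016667
0.016667 0.016667 0.016667 0.950000
0.016667 0.016667 0.950000 0.016667
0.050000 0.850000 0.050000 0.050000
0.150000 0.550000 0.150000 0.150000

MOTIF NFYB
letter-probability matrix: alength= 4 w= 16 nsites= 100 E= 0
0.150000 0.550000 0.150000 0.150000
0.150000 0.150000 0.150000 0.550000
0.150000 0.150000 0.550000 0.150000
0.850000 0.050000 0.050000 0.050000
0.016667 0.016667 0.950000 0.016667
0.016667 0.950000 0.016667 0.016667
0.016667 0.950000 0.016667 0.016667
0.950000 0.016667 0.016667 0.016667
0.950000 0.016667 0.016667 0.016667
0.016667 0.016667 0.016667 0.950000
0.016667 0.950000 0.016667 0.016667
0.950000 0.016667 0.016667 0.016667
0.050000 0.050000 0.850000 0.050000
0.550000 0.150000 0.150000 0.150000
0.150000 0.150000 0.550000 0.150000
0.150000 0.550000 0.150000 0.150000

MOTIF SP1
letter-probability matrix: alength= 4 w= 11 nsites= 100 E= 0
0.150000 0.150000 0.550000 0.150000
0.050000 0.050000 0.850000 0.050000
0.016667 0.016667 0.950000 0.016667
0.016667 0.016667 0.950000 0.016667
0.016667 0.016667 0.950000 0.016667
0.016667 0.950000 0.016667 0.016667
0.016667 0.016667 0.950000 0.016667
0.016667 0.016667 0.950000 0.016667
0.016667 0.016667 0.950000 0.016667
0.050000 0.050000 0.850000 0.050000
0.150000 0.550000 0.150000 0.150000

MOTIF SRF
letter-probability matrix: alength= 4 w= 16 nsites= 100 E= 0
0.150000 0.150000 0.550000 0.150000
0.150000 0.150000 0.150000 0.550000
0.050000 0.850000 0.050000 0.050000
0.016667 0.950000 0.016667 0.016667
0.950000 0.016667 0.016667 0.016667
0.016667 0.016667 0.016667 0.950000
0.950000 0.016667 0.016667 0.016667
0.016667 0.016667 0.016667 0.950000
0.950000 0.016667 0.016667 0.016667
0.016667 0.016667 0.016667 0.950000
0.016667 0.016667 0.950000 0.016667
0.016667 0.016667 0.950000 0.016667
0.950000 0.016667 0.016667 0.016667
0.050000 0.850000 0.050000 0.050000
0.150000 0.150000 0.150000 0.550000
0.150000 0.150000 0.550000 0.150000

MOTIF STAT1
letter-probability matrix: alength= 4 w= 11 nsites= 100 E= 0
0.150000 0.150000 0.150000 0.550000
0.050000 0.050000 0.050000 0.850000
0.016667 0.016667 0.016667 0.950000
0.016667 0.950000 0.016667 0.016667
0.016667 0.950000 0.016667 0.016667
0.250000 0.250000 0.250000 0.250000
0.016667 0.016667 0.950000 0.016667
0.016667 0.016667 0.950000 0.016667
0.950000 0.016667 0.016667 0.016667
0.850000 0.050000 0.050000 0.050000
0.550000 0.150000 0.150000 0.150000

MOTIF YY1
letter-probability matrix: alength= 4 w= 12 nsites= 100 E= 0
0.150000 0.550000 0.150000 0.150000
0.550000 0.150000 0.150000 0.150000
0.850000 0.050000 0.050000 0.050000
0.016667 0.016667 0.950000 0.016667
0.950000 0.016667 0.016667 0.016667
0.016667 0.016667 0.016667 0.950000
0.016667 0.016667 0.950000 0.016667
0.016667 0.016667 0.950000 0.016667
0.016667 0.950000 0.016667 0.016667
0.050000 0.050000 0.850000 0.050000
0.150000 0.150000 0.550000 0.150000
0.150000 0.550000 0.150000 0.150000

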