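MEME version 4

ALPHABET= ACGT

strands: + -

Background letter frequencies
A 0.25 C 0.25 G 0.25 T 0.25

MOTIF gata GATA_SYNTHETIC
letter-probability matrix: alength= 4 w= 8 nsites= 100 E= 0
 0.600000  0.100000  0.100000  0.200000
 0.940000  0.020000  0.020000  0.020000
 0.020000  0.020000  0.940000  0.020000
 0.960000  0.013333  0.013333  0.013333
 0.013333  0.013333  0.013333  0.960000
 0.940000  0.020000  0.020000  0.020000
 0.700000  0.100000  0.150000  0.050000
 0.940000  0.020000  0.020000  0.020000

MOTIF er_half ER_HALF_SITE_SYNTHETIC
letter-probability matrix: alength= 4 w= 8 nsites= 100 E= 0
 0.500000  0.150000  0.200000  0.150000
 0.940000  0.020000  0.020000  0.020000
 0.020000  0.020000  0.940000  0.020000
 0.020000  0.020000  0.940000  0.020000
 0.013333  0.013333  0.013333  0.960000
 0.020000  0.940000  0.020000  0.020000
 0.940000  0.020000  0.020000  0.020000
 0.600000  0.150000  0.150000  0.100000
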