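# Synthetic codon usage table emulating Triticum aestivum
# Generated by a compositional model (uniform family weights,
# species-typical codon multipliers, third-position GC tilt).
# Target GC3s: 0.62. NOT a Codon Usage Database snapshot;
# substitute a genuine cusp table for production host screening.
#Coding GC synthetic
Codon AA Fraction Frequency Number
AAA K 0.302 18.087 18087
AAC N 0.606 26.405 26405
AAG K 0.698 41.709 41709
AAT N 0.394 17.176 17176
ACA T 0.197 10.984 10984
ACC T 0.303 16.887 16887
ACG T 0.303 16.887 16887
ACT T 0.197 10.984 10984
AGA R 0.131 6.924 6924
AGC S 0.202 14.124 14124
AGG R 0.202 10.644 10644
AGT S 0.131 9.187 9187
ATA I 0.283 15.758 15758
ATC I 0.435 24.226 24226
ATG M 1.000 23.311 23311
ATT I 0.283 15.758 15758
CAA Q 0.394 15.578 15578
CAC H 0.606 14.124 14124
CAG Q 0.606 23.949 23949
CAT H 0.394 9.187 9187
CCA P 0.197 9.786 9786
CCC P 0.303 15.045 15045
CCG P 0.303 15.045 15045
CCT P 0.197 9.786 9786
CGA R 0.131 6.924 6924
CGC R 0.202 10.644 10644
CGG R 0.202 10.644 10644
CGT R 0.131 6.924 6924
CTA L 0.122 11.457 11457
CTC L 0.262 24.659 24659
CTG L 0.187 17.613 17613
CTT L 0.122 11.457 11457
GAA E 0.317 20.255 20255
GAC D 0.606 32.546 32546
GAG E 0.683 43.595 43595
GAT D 0.394 21.170 21170
GCA A 0.171 13.355 13355
GCC A 0.395 30.797 30797
GCG A 0.263 20.532 20532
GCT A 0.171 13.355 13355
GGA G 0.171 11.447 11447
GGC G 0.395 26.398 26398
GGG G 0.263 17.599 17599
GGT G 0.171 11.447 11447
GTA V 0.197 13.581 13581
GTC V 0.303 20.878 20878
GTG V 0.303 20.878 20878
GTT V 0.197 13.581 13581
TAA * 0.529 0.900 900
TAC Y 0.606 18.422 18422
TAG * 0.176 0.300 300
TAT Y 0.394 11.983 11983
TCA S 0.131 9.187 9187
TCC S 0.202 14.124 14124
TCG S 0.202 14.124 14124
TCT S 0.131 9.187 9187
TGA * 0.294 0.500 500
TGC C 0.606 9.825 9825
TGG W 1.000 12.162 12162
TGT C 0.394 6.391 6391
TTA L 0.122 11.457 11457
TTC F 0.667 27.020 27020
TTG L 0.187 17.613 17613
TTT F 0.333 13.520 13520
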