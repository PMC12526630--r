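# Synthetic codon usage table emulating Zea mays
# Generated by a compositional model (uniform family weights,
# species-typical codon multipliers, third-position GC tilt).
# Target GC3s: 0.63. NOT a Codon Usage Database snapshot;
# substitute a genuine cusp table for production host screening.
#Coding GC synthetic
Codon AA Fraction Frequency Number
AAA K 0.295 17.653 17653
AAC N 0.614 26.764 26764
AAG K 0.705 42.144 42144
AAT N 0.386 16.816 16816
ACA T 0.193 10.755 10755
ACC T 0.307 17.117 17117
ACG T 0.307 17.117 17117
ACT T 0.193 10.755 10755
AGA R 0.129 6.779 6779
AGC S 0.205 14.316 14316
AGG R 0.205 10.789 10789
AGT S 0.129 8.995 8995
ATA I 0.278 15.521 15521
ATC I 0.443 24.702 24702
ATG M 1.000 23.311 23311
ATT I 0.278 15.521 15521
CAA Q 0.386 15.252 15252
CAC H 0.614 14.316 14316
CAG Q 0.614 24.274 24274
CAT H 0.386 8.995 8995
CCA P 0.193 9.581 9581
CCC P 0.307 15.249 15249
CCG P 0.307 15.249 15249
CCT P 0.193 9.581 9581
CGA R 0.129 6.779 6779
CGC R 0.205 10.789 10789
CGG R 0.205 10.789 10789
CGT R 0.129 6.779 6779
CTA L 0.115 10.797 10797
CTC L 0.237 22.340 22340
CTG L 0.237 22.340 22340
CTT L 0.115 10.797 10797
GAA E 0.310 19.779 19779
GAC D 0.614 32.988 32988
GAG E 0.690 44.071 44071
GAT D 0.386 20.727 20727
GCA A 0.163 12.714 12714
GCC A 0.415 32.376 32376
GCG A 0.259 20.235 20235
GCT A 0.163 12.714 12714
GGA G 0.167 11.188 11188
GGC G 0.399 26.709 26709
GGG G 0.266 17.806 17806
GGT G 0.167 11.188 11188
GTA V 0.193 13.297 13297
GTC V 0.307 21.162 21162
GTG V 0.307 21.162 21162
GTT V 0.193 13.297 13297
TAA * 0.529 0.900 900
TAC Y 0.614 18.673 18673
TAG * 0.176 0.300 300
TAT Y 0.386 11.732 11732
TCA S 0.129 8.995 8995
TCC S 0.205 14.316 14316
TCG S 0.205 14.316 14316
TCT S 0.129 8.995 8995
TGA * 0.294 0.500 500
TGC C 0.614 9.959 9959
TGG W 1.000 12.162 12162
TGT C 0.386 6.257 6257
TTA L 0.115 10.797 10797
TTC F 0.674 27.331 27331
TTG L 0.182 17.184 17184
TTT F 0.326 13.210 13210
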