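# Synthetic codon usage table emulating Arabidopsis thaliana
# Generated by a compositional model (uniform family weights,
# species-typical codon multipliers, third-position GC tilt).
# Target GC3s: 0.42. NOT a Codon Usage Database snapshot;
# substitute a genuine cusp table for production host screening.
#Coding GC synthetic
Codon AA Fraction Frequency Number
AAA K 0.477 28.495 28495
AAC N 0.440 19.161 19161
AAG K 0.523 31.301 31301
AAT N 0.560 24.420 24420
ACA T 0.280 15.617 15617
ACC T 0.220 12.254 12254
ACG T 0.220 12.254 12254
ACT T 0.280 15.617 15617
AGA R 0.292 15.415 15415
AGC S 0.139 9.705 9705
AGG R 0.128 6.720 6720
AGT S 0.177 12.369 12369
ATA I 0.359 20.018 20018
ATC I 0.282 15.707 15707
ATG M 1.000 23.311 23311
ATT I 0.359 20.018 20018
CAA Q 0.560 22.148 22148
CAC H 0.440 10.249 10249
CAG Q 0.440 17.378 17378
CAT H 0.560 13.062 13062
CCA P 0.280 13.914 13914
CCC P 0.220 10.917 10917
CCG P 0.220 10.917 10917
CCT P 0.280 13.914 13914
CGA R 0.162 8.564 8564
CGC R 0.128 6.720 6720
CGG R 0.128 6.720 6720
CGT R 0.162 8.564 8564
CTA L 0.174 16.381 16381
CTC L 0.136 12.853 12853
CTG L 0.136 12.853 12853
CTT L 0.243 22.934 22934
GAA E 0.560 35.778 35778
GAC D 0.376 20.218 20218
GAG E 0.440 28.073 28073
GAT D 0.624 33.498 33498
GCA A 0.246 19.178 19178
GCC A 0.193 15.048 15048
GCG A 0.193 15.048 15048
GCT A 0.369 28.767 28767
GGA G 0.280 18.741 18741
GGC G 0.220 14.705 14705
GGG G 0.220 14.705 14705
GGT G 0.280 18.741 18741
GTA V 0.280 19.309 19309
GTC V 0.220 15.150 15150
GTG V 0.220 15.150 15150
GTT V 0.280 19.309 19309
TAA * 0.529 0.900 900
TAC Y 0.440 13.368 13368
TAG * 0.176 0.300 300
TAT Y 0.560 17.037 17037
TCA S 0.177 12.369 12369
TCC S 0.139 9.705 9705
TCG S 0.139 9.705 9705
TCT S 0.230 16.079 16079
TGA * 0.294 0.500 500
TGC C 0.440 7.130 7130
TGG W 1.000 12.162 12162
TGT C 0.560 9.087 9087
TTA L 0.174 16.381 16381
TTC F 0.440 17.824 17824
TTG L 0.136 12.853 12853
TTT F 0.560 22.716 22716
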