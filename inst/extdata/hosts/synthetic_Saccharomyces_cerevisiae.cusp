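# Synthetic codon usage table emulating Saccharomyces cerevisiae
# Generated by a compositional model (uniform family weights,
# species-typical codon multipliers, third-position GC tilt).
# Target GC3s: 0.38. NOT a Codon Usage Database snapshot;
# substitute a genuine cusp table for production host screening.
#Coding GC synthetic
Codon AA Fraction Frequency Number
AAA K 0.579 34.598 34598
AAC N 0.421 18.365 18365
AAG K 0.421 25.199 25199
AAT N 0.579 25.215 25215
ACA T 0.289 16.126 16126
ACC T 0.211 11.745 11745
ACG T 0.211 11.745 11745
ACT T 0.289 16.126 16126
AGA R 0.575 30.291 30291
AGC S 0.126 8.804 8804
AGG R 0.140 7.354 7354
AGT S 0.173 12.088 12088
ATA I 0.320 17.819 17819
ATC I 0.233 12.978 12978
ATG M 1.000 23.311 23311
ATT I 0.448 24.946 24946
CAA Q 0.579 22.870 22870
CAC H 0.421 9.823 9823
CAG Q 0.421 16.657 16657
CAT H 0.579 13.487 13487
CCA P 0.449 22.286 22286
CCC P 0.163 8.116 8116
CCG P 0.163 8.116 8116
CCT P 0.224 11.143 11143
CGA R 0.038 2.019 2019
CGC R 0.028 1.471 1471
CGG R 0.028 1.471 1471
CGT R 0.192 10.097 10097
CTA L 0.169 15.940 15940
CTC L 0.123 11.609 11609
CTG L 0.123 11.609 11609
CTT L 0.169 15.940 15940
GAA E 0.579 36.944 36944
GAC D 0.421 22.636 22636
GAG E 0.421 26.907 26907
GAT D 0.579 31.079 31079
GCA A 0.247 19.237 19237
GCC A 0.180 14.011 14011
GCG A 0.180 14.011 14011
GCT A 0.394 30.780 30780
GGA G 0.202 13.495 13495
GGC G 0.147 9.829 9829
GGG G 0.147 9.829 9829
GGT G 0.504 33.738 33738
GTA V 0.259 17.870 17870
GTC V 0.189 13.015 13015
GTG V 0.189 13.015 13015
GTT V 0.363 25.018 25018
TAA * 0.529 0.900 900
TAC Y 0.421 12.813 12813
TAG * 0.176 0.300 300
TAT Y 0.579 17.592 17592
TCA S 0.173 12.088 12088
TCC S 0.126 8.804 8804
TCG S 0.126 8.804 8804
TCT S 0.277 19.342 19342
TGA * 0.294 0.500 500
TGC C 0.421 6.834 6834
TGG W 1.000 12.162 12162
TGT C 0.579 9.382 9382
TTA L 0.169 15.940 15940
TTC F 0.421 17.084 17084
TTG L 0.246 23.219 23219
TTT F 0.579 23.456 23456
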