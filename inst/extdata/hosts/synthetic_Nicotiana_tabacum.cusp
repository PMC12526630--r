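# Synthetic codon usage table emulating Nicotiana tabacum
# Generated by a compositional model (uniform family weights,
# species-typical codon multipliers, third-position GC tilt).
# Target GC3s: 0.41. NOT a Codon Usage Database snapshot;
# substitute a genuine cusp table for production host screening.
#Coding GC synthetic
Codon AA Fraction Frequency Number
AAA K 0.511 30.563 30563
AAC N 0.424 18.473 18473
AAG K 0.489 29.234 29234
AAT N 0.576 25.107 25107
ACA T 0.288 16.057 16057
ACC T 0.212 11.814 11814
ACG T 0.212 11.814 11814
ACT T 0.288 16.057 16057
AGA R 0.276 14.520 14520
AGC S 0.141 9.881 9881
AGG R 0.127 6.677 6677
AGT S 0.192 13.429 13429
ATA I 0.366 20.375 20375
ATC I 0.269 14.992 14992
ATG M 1.000 23.311 23311
ATT I 0.366 20.375 20375
CAA Q 0.576 22.772 22772
CAC H 0.424 9.881 9881
CAG Q 0.424 16.755 16755
CAT H 0.576 13.429 13429
CCA P 0.362 17.958 17958
CCC P 0.190 9.438 9438
CCG P 0.190 9.438 9438
CCT P 0.258 12.827 12827
CGA R 0.172 9.075 9075
CGC R 0.127 6.677 6677
CGG R 0.127 6.677 6677
CGT R 0.172 9.075 9075
CTA L 0.184 17.365 17365
CTC L 0.136 12.776 12776
CTG L 0.136 12.776 12776
CTT L 0.184 17.365 17365
GAA E 0.576 36.785 36785
GAC D 0.424 22.769 22769
GAG E 0.424 27.066 27066
GAT D 0.576 30.946 30946
GCA A 0.258 20.157 20157
GCC A 0.190 14.831 14831
GCG A 0.190 14.831 14831
GCT A 0.362 28.220 28220
GGA G 0.362 24.189 24189
GGC G 0.190 12.712 12712
GGG G 0.190 12.712 12712
GGT G 0.258 17.278 17278
GTA V 0.288 19.852 19852
GTC V 0.212 14.607 14607
GTG V 0.212 14.607 14607
GTT V 0.288 19.852 19852
TAA * 0.529 0.900 900
TAC Y 0.424 12.888 12888
TAG * 0.176 0.300 300
TAT Y 0.576 17.517 17517
TCA S 0.192 13.429 13429
TCC S 0.141 9.881 9881
TCG S 0.141 9.881 9881
TCT S 0.192 13.429 13429
TGA * 0.294 0.500 500
TGC C 0.424 6.874 6874
TGG W 1.000 12.162 12162
TGT C 0.576 9.342 9342
TTA L 0.184 17.365 17365
TTC F 0.424 17.184 17184
TTG L 0.176 16.609 16609
TTT F 0.576 23.356 23356
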