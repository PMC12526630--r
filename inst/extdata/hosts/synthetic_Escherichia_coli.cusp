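# Synthetic codon usage table emulating Escherichia coli
# Generated by a compositional model (uniform family weights,
# species-typical codon multipliers, third-position GC tilt).
# Target GC3s: 0.55. NOT a Codon Usage Database snapshot;
# substitute a genuine cusp table for production host screening.
#Coding GC synthetic
Codon AA Fraction Frequency Number
AAA K 0.570 34.055 34055
AAC N 0.547 23.855 23855
AAG K 0.430 25.741 25741
AAT N 0.453 19.725 19725
ACA T 0.226 12.615 12615
ACC T 0.274 15.256 15256
ACG T 0.274 15.256 15256
ACT T 0.226 12.615 12615
AGA R 0.010 0.504 504
AGC S 0.189 13.243 13243
AGG R 0.017 0.871 871
AGT S 0.157 10.950 10950
ATA I 0.083 4.627 4627
ATC I 0.502 27.980 27980
ATG M 1.000 23.311 23311
ATT I 0.415 23.136 23136
CAA Q 0.453 17.890 17890
CAC H 0.547 12.760 12760
CAG Q 0.547 21.636 21636
CAT H 0.453 10.551 10551
CCA P 0.280 13.902 13902
CCC P 0.102 5.044 5044
CCG P 0.339 16.813 16813
CCT P 0.280 13.902 13902
CGA R 0.137 7.201 7201
CGC R 0.330 17.417 17417
CGG R 0.165 8.708 8708
CGT R 0.342 18.002 18002
CTA L 0.016 1.503 1503
CTC L 0.129 12.119 12119
CTG L 0.514 48.474 48474
CTT L 0.106 10.021 10021
GAA E 0.554 35.350 35350
GAC D 0.547 29.403 29403
GAG E 0.446 28.501 28501
GAT D 0.453 24.313 24313
GCA A 0.226 17.661 17661
GCC A 0.274 21.359 21359
GCG A 0.274 21.359 21359
GCT A 0.226 17.661 17661
GGA G 0.105 7.007 7007
GGC G 0.317 21.184 21184
GGG G 0.317 21.184 21184
GGT G 0.262 17.516 17516
GTA V 0.226 15.597 15597
GTC V 0.274 18.862 18862
GTG V 0.274 18.862 18862
GTT V 0.226 15.597 15597
TAA * 0.529 0.900 900
TAC Y 0.547 16.643 16643
TAG * 0.176 0.300 300
TAT Y 0.453 13.762 13762
TCA S 0.157 10.950 10950
TCC S 0.189 13.243 13243
TCG S 0.151 10.594 10594
TCT S 0.157 10.950 10950
TGA * 0.294 0.500 500
TGC C 0.547 8.876 8876
TGG W 1.000 12.162 12162
TGT C 0.453 7.340 7340
TTA L 0.106 10.021 10021
TTC F 0.547 22.191 22191
TTG L 0.129 12.119 12119
TTT F 0.453 18.349 18349
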