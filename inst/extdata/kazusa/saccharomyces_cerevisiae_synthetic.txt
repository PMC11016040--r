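# codon usage table: saccharomyces_cerevisiae_synthetic
# fields: [triplet] [frequency: per thousand] ([number])
AAA 28.0(  2803)  AAC 18.6(  1860)  AAG 18.0(  1796)  AAU 27.6(  2759)
ACA 17.5(  1746)  ACC 9.0(   895)  ACG 10.6(  1058)  ACU 15.7(  1570)
AGA 9.8(   981)  AGC 8.3(   826)  AGG 6.0(   603)  AGU 18.6(  1857)
AUA 31.0(  3099)  AUC 16.2(  1618)  AUG 25.9(  2586)  AUU 35.4(  3539)
CAA 25.0(  2499)  CAC 7.7(   768)  CAG 16.1(  1611)  CAU 13.3(  1331)
CCA 12.7(  1266)  CCC 8.5(   850)  CCG 7.6(   757)  CCU 14.7(  1474)
CGA 10.4(  1036)  CGC 5.9(   587)  CGG 5.7(   574)  CGU 11.2(  1121)
CUA 19.4(  1941)  CUC 10.7(  1074)  CUG 12.7(  1271)  CUU 25.4(  2536)
GAA 33.2(  3317)  GAC 17.0(  1702)  GAG 18.5(  1849)  GAU 24.2(  2424)
GCA 20.2(  2019)  GCC 12.1(  1211)  GCG 11.9(  1194)  GCU 19.9(  1991)
GGA 20.9(  2090)  GGC 13.8(  1384)  GGG 10.1(  1008)  GGU 22.1(  2206)
GUA 18.3(  1827)  GUC 10.2(  1020)  GUG 9.6(   958)  GUU 19.7(  1966)
UAA 0.7(    68)  UAC 11.5(  1147)  UAG 0.7(    71)  UAU 21.4(  2136)
UCA 16.4(  1636)  UCC 9.7(   967)  UCG 8.8(   884)  UCU 15.5(  1548)
UGA 0.7(    70)  UGC 4.4(   440)  UGG 19.6(  1963)  UGU 6.9(   692)
UUA 21.7(  2174)  UUC 25.0(  2499)  UUG 11.9(  1191)  UUU 40.6(  4060)
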