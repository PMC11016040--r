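# codon usage table: escherichia_coli_synthetic
# fields: [triplet] [frequency: per thousand] ([number])
AAA 19.1(  1912)  AAC 24.4(  2443)  AAG 26.0(  2603)  AAU 23.1(  2309)
ACA 11.1(  1115)  ACC 14.6(  1463)  ACG 16.9(  1688)  ACU 11.5(  1145)
AGA 8.1(   807)  AGC 13.8(  1380)  AGG 10.0(   995)  AGU 11.2(  1119)
AUA 26.1(  2606)  AUC 31.9(  3188)  AUG 27.2(  2718)  AUU 25.7(  2566)
CAA 17.7(  1771)  CAC 11.2(  1121)  CAG 21.9(  2190)  CAU 10.6(  1058)
CCA 9.7(   974)  CCC 13.3(  1326)  CCG 11.7(  1167)  CCU 9.3(   927)
CGA 7.0(   697)  CGC 7.3(   726)  CGG 8.0(   796)  CGU 7.8(   776)
CUA 13.3(  1333)  CUC 18.9(  1895)  CUG 18.2(  1821)  CUU 16.8(  1678)
GAA 24.6(  2460)  GAC 21.8(  2180)  GAG 26.3(  2627)  GAU 18.5(  1848)
GCA 12.9(  1286)  GCC 17.4(  1743)  GCG 17.1(  1708)  GCU 16.4(  1641)
GGA 13.8(  1381)  GGC 16.5(  1648)  GGG 20.2(  2019)  GGU 16.9(  1685)
GUA 13.0(  1295)  GUC 16.6(  1656)  GUG 16.1(  1615)  GUU 13.4(  1342)
UAA 0.6(    63)  UAC 16.7(  1670)  UAG 0.8(    83)  UAU 15.8(  1576)
UCA 11.3(  1130)  UCC 14.1(  1406)  UCG 13.5(  1347)  UCU 12.4(  1236)
UGA 0.8(    82)  UGC 5.5(   548)  UGG 19.8(  1985)  UGU 5.1(   514)
UUA 15.7(  1569)  UUC 32.2(  3220)  UUG 18.8(  1880)  UUU 32.5(  3246)
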