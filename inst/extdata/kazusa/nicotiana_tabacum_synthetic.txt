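# codon usage table: nicotiana_tabacum_synthetic
# fields: [triplet] [frequency: per thousand] ([number])
AAA 28.1(  2806)  AAC 17.0(  1702)  AAG 17.9(  1789)  AAU 30.0(  3002)
ACA 18.7(  1870)  ACC 9.2(   916)  ACG 9.1(   910)  ACU 16.7(  1669)
AGA 9.9(   989)  AGC 9.2(   920)  AGG 6.7(   672)  AGU 17.0(  1704)
AUA 30.3(  3032)  AUC 17.9(  1789)  AUG 27.3(  2732)  AUU 32.9(  3291)
CAA 25.1(  2511)  CAC 8.3(   834)  CAG 14.9(  1492)  CAU 13.0(  1302)
CCA 13.0(  1304)  CCC 7.6(   756)  CCG 9.1(   909)  CCU 14.1(  1406)
CGA 10.6(  1055)  CGC 5.7(   568)  CGG 6.0(   604)  CGU 10.3(  1034)
CUA 23.0(  2296)  CUC 11.1(  1112)  CUG 11.9(  1192)  CUU 22.0(  2197)
GAA 32.0(  3202)  GAC 16.1(  1606)  GAG 19.1(  1910)  GAU 24.7(  2469)
GCA 20.1(  2013)  GCC 11.4(  1136)  GCG 11.8(  1182)  GCU 21.9(  2189)
GGA 22.9(  2285)  GGC 12.7(  1274)  GGG 10.6(  1059)  GGU 21.8(  2182)
GUA 18.3(  1833)  GUC 9.8(   981)  GUG 9.9(   988)  GUU 19.0(  1904)
UAA 0.7(    74)  UAC 12.3(  1233)  UAG 0.7(    72)  UAU 20.2(  2017)
UCA 16.2(  1624)  UCC 9.4(   937)  UCG 9.2(   923)  UCU 15.9(  1594)
UGA 0.6(    63)  UGC 4.1(   414)  UGG 20.4(  2041)  UGU 6.6(   655)
UUA 20.8(  2079)  UUC 24.3(  2430)  UUG 13.3(  1329)  UUU 39.4(  3940)
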