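# codon usage table: arabidopsis_thaliana_synthetic
# fields: [triplet] [frequency: per thousand] ([number])
AAA 27.0(  2695)  AAC 18.3(  1827)  AAG 19.7(  1966)  AAU 29.0(  2900)
ACA 16.9(  1693)  ACC 10.5(  1051)  ACG 10.8(  1079)  ACU 15.7(  1572)
AGA 9.3(   933)  AGC 10.8(  1079)  AGG 6.3(   633)  AGU 14.9(  1488)
AUA 29.0(  2904)  AUC 19.0(  1901)  AUG 26.9(  2691)  AUU 32.1(  3214)
CAA 24.0(  2396)  CAC 8.7(   873)  CAG 15.2(  1516)  CAU 12.9(  1291)
CCA 13.9(  1389)  CCC 8.4(   838)  CCG 7.5(   746)  CCU 14.0(  1401)
CGA 10.2(  1025)  CGC 6.4(   640)  CGG 5.7(   570)  CGU 10.1(  1007)
CUA 22.2(  2215)  CUC 12.6(  1259)  CUG 13.6(  1357)  CUU 22.2(  2221)
GAA 31.0(  3101)  GAC 15.0(  1504)  GAG 20.5(  2053)  GAU 25.5(  2550)
GCA 20.7(  2070)  GCC 10.9(  1093)  GCG 12.2(  1216)  GCU 19.9(  1993)
GGA 19.9(  1987)  GGC 13.0(  1301)  GGG 14.5(  1445)  GGU 20.8(  2078)
GUA 17.5(  1748)  GUC 11.3(  1130)  GUG 11.1(  1106)  GUU 18.7(  1874)
UAA 0.8(    78)  UAC 12.7(  1274)  UAG 0.7(    74)  UAU 20.7(  2069)
UCA 17.1(  1710)  UCC 10.0(   996)  UCG 10.6(  1061)  UCU 15.4(  1539)
UGA 0.8(    77)  UGC 4.4(   439)  UGG 18.7(  1873)  UGU 6.3(   632)
UUA 19.5(  1949)  UUC 24.6(  2463)  UUG 12.1(  1207)  UUU 39.4(  3937)
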