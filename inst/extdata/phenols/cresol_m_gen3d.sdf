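cresol_m
 OpenBabel09282620383D

 16 16  0  0  0  0  0  0  0  0999 V2000
    2.5253    1.1876   -0.0006 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.2685    0.3705   -0.0018 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.3087   -1.0294    0.0049 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.1239   -1.7705   -0.0022 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.1106   -1.1208   -0.0135 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.1481    0.2698   -0.0157 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.3300    0.9497   -0.0218 O   0  0  0  0  0  0  0  0  0  0  0  0
    0.0253    1.0148   -0.0116 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.4188    0.5543    0.0068 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.5579    1.8266    0.8874 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.5655    1.8153   -0.8967 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.2622   -1.5530    0.0149 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.1656   -2.8567    0.0007 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.0220   -1.7095   -0.0211 H   0  0  0  0  0  0  0  0  0  0  0  0
   -3.0563    0.3058   -0.0018 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0326    2.1002   -0.0157 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  1  9  1  0  0  0  0
  1 10  1  0  0  0  0
  1 11  1  0  0  0  0
  2  3  1  0  0  0  0
  2  8  2  0  0  0  0
  3  4  2  0  0  0  0
  3 12  1  0  0  0  0
  4  5  1  0  0  0  0
  4 13  1  0  0  0  0
  5  6  2  0  0  0  0
  5 14  1  0  0  0  0
  6  7  1  0  0  0  0
  6  8  1  0  0  0  0
  7 15  1  0  0  0  0
  8 16  1  0  0  0  0
M  END
$$$$
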