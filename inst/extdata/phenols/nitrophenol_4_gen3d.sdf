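nitrophenol_4
 OpenBabel09282620383D

 15 15  0  0  0  0  0  0  0  0999 V2000
    2.2454    0.0168    0.0158 O   0  0  0  0  0  0  0  0  0  0  0  0
    0.8831   -0.0130    0.0106 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.1829   -1.2175    0.0029 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.2148   -1.2008   -0.0088 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.8928    0.0281   -0.0130 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.1812    1.2356   -0.0008 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.2138    1.2079    0.0115 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.3607    0.0498   -0.0334 N   0  3  0  0  0  0  0  0  0  0  0  0
   -3.9528   -1.0390   -0.0479 O   0  0  0  0  0  0  0  0  0  0  0  0
   -3.9223    1.1548   -0.0364 O   0  5  0  0  0  0  0  0  0  0  0  0
    2.5843   -0.8932   -0.0119 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.7035   -2.1705    0.0055 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7567   -2.1440   -0.0155 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.6918    2.1960   -0.0025 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.7800    2.1361    0.0198 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  1 11  1  0  0  0  0
  2  3  1  0  0  0  0
  2  7  2  0  0  0  0
  3  4  2  0  0  0  0
  3 12  1  0  0  0  0
  4  5  1  0  0  0  0
  4 13  1  0  0  0  0
  5  6  2  0  0  0  0
  5  8  1  0  0  0  0
  6  7  1  0  0  0  0
  6 14  1  0  0  0  0
  7 15  1  0  0  0  0
  8  9  2  0  0  0  0
  8 10  1  0  0  0  0
M  CHG  2   8   1  10  -1
M  END
$$$$
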