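dinitrophenol_24
 OpenBabel09282620383D

 17 17  0  0  0  0  0  0  0  0999 V2000
    2.2948   -0.0668   -0.0170 O   0  0  0  0  0  0  0  0  0  0  0  0
    0.9329   -0.0264    0.0110 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.2083   -1.2183    0.0050 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.1909   -1.1860   -0.0052 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.8645    0.0462   -0.0146 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.1506    1.2504   -0.0045 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.2485    1.1927    0.0162 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.9839    2.4438    0.0396 N   0  3  0  0  0  0  0  0  0  0  0  0
    1.7013    2.6660    1.0235 O   0  0  0  0  0  0  0  0  0  0  0  0
    0.7754    3.2280   -0.8964 O   0  5  0  0  0  0  0  0  0  0  0  0
   -3.3335    0.0670   -0.0314 N   0  3  0  0  0  0  0  0  0  0  0  0
   -3.9231   -1.0221   -0.0444 O   0  0  0  0  0  0  0  0  0  0  0  0
   -3.8907    1.1724   -0.0299 O   0  5  0  0  0  0  0  0  0  0  0  0
    2.6068   -0.9884   -0.0008 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.7113   -2.1823    0.0047 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7395   -2.1275   -0.0106 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.6600    2.2127   -0.0103 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  1 14  1  0  0  0  0
  2  3  1  0  0  0  0
  2  7  2  0  0  0  0
  3  4  2  0  0  0  0
  3 15  1  0  0  0  0
  4  5  1  0  0  0  0
  4 16  1  0  0  0  0
  5  6  2  0  0  0  0
  5 11  1  0  0  0  0
  6  7  1  0  0  0  0
  6 17  1  0  0  0  0
  7  8  1  0  0  0  0
  8  9  2  0  0  0  0
  8 10  1  0  0  0  0
 11 12  2  0  0  0  0
 11 13  1  0  0  0  0
M  CHG  4   8   1  10  -1  11   1  13  -1
M  END
$$$$
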