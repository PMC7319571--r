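chlorophenol_2
 OpenBabel09282620383D

 13 13  0  0  0  0  0  0  0  0999 V2000
    0.5632   -2.0264    0.0033 O   0  0  0  0  0  0  0  0  0  0  0  0
   -0.2459   -0.9231    0.0026 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.6328   -1.0810    0.0145 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.4583    0.0457    0.0109 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.9002    1.3245   -0.0063 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.5130    1.4808   -0.0163 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.3163    0.3571   -0.0105 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.0257    0.5918   -0.0193 Cl  0  0  0  0  0  0  0  0  0  0  0  0
    0.0148   -2.8270   -0.0077 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.0864   -2.0672    0.0278 H   0  0  0  0  0  0  0  0  0  0  0  0
   -3.5392   -0.0730    0.0209 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.5449    2.2001   -0.0107 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0836    2.4791   -0.0286 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  1  9  1  0  0  0  0
  2  3  1  0  0  0  0
  2  7  2  0  0  0  0
  3  4  2  0  0  0  0
  3 10  1  0  0  0  0
  4  5  1  0  0  0  0
  4 11  1  0  0  0  0
  5  6  2  0  0  0  0
  5 12  1  0  0  0  0
  6  7  1  0  0  0  0
  6 13  1  0  0  0  0
  7  8  1  0  0  0  0
M  END
$$$$
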