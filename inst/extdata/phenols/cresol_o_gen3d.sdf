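cresol_o
 OpenBabel09282620383D

 16 16  0  0  0  0  0  0  0  0999 V2000
   -1.7501   -1.6148    0.0032 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.5024   -0.7820    0.0004 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.7614   -1.3866   -0.0072 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.9197   -0.6063   -0.0040 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.8256    0.7848    0.0063 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.5734    1.3993    0.0087 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.5784    0.6141    0.0048 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.8147    1.1964    0.0057 O   0  0  0  0  0  0  0  0  0  0  0  0
   -1.5196   -2.6848    0.0149 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.3436   -1.4093   -0.8936 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.3493   -1.3933    0.8926 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.8516   -2.4701   -0.0148 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.8953   -1.0855   -0.0089 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.7291    1.3887    0.0126 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.5159    2.4832    0.0154 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7022    2.1603   -0.0092 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  1  9  1  0  0  0  0
  1 10  1  0  0  0  0
  1 11  1  0  0  0  0
  2  3  1  0  0  0  0
  2  7  2  0  0  0  0
  3  4  2  0  0  0  0
  3 12  1  0  0  0  0
  4  5  1  0  0  0  0
  4 13  1  0  0  0  0
  5  6  2  0  0  0  0
  5 14  1  0  0  0  0
  6  7  1  0  0  0  0
  6 15  1  0  0  0  0
  7  8  1  0  0  0  0
  8 16  1  0  0  0  0
M  END
$$$$
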