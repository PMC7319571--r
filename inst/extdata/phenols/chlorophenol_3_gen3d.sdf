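chlorophenol_3
 OpenBabel09282620383D

 13 13  0  0  0  0  0  0  0  0999 V2000
    2.5962   -1.4037   -0.0028 O   0  0  0  0  0  0  0  0  0  0  0  0
    1.6233   -0.4479   -0.0036 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.9411    0.9085   -0.0008 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.9142    1.8542   -0.0003 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.4188    1.4379   -0.0019 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.7198    0.0755   -0.0048 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.3637   -0.4340   -0.0056 Cl  0  0  0  0  0  0  0  0  0  0  0  0
    0.2993   -0.8735   -0.0064 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.4646   -0.9685    0.0087 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.9733    1.2449    0.0005 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.1506    2.9154    0.0016 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.2158    2.1769   -0.0007 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.0717   -1.9349   -0.0090 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  1  9  1  0  0  0  0
  2  3  1  0  0  0  0
  2  8  2  0  0  0  0
  3  4  2  0  0  0  0
  3 10  1  0  0  0  0
  4  5  1  0  0  0  0
  4 11  1  0  0  0  0
  5  6  2  0  0  0  0
  5 12  1  0  0  0  0
  6  7  1  0  0  0  0
  6  8  1  0  0  0  0
  8 13  1  0  0  0  0
M  END
$$$$
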