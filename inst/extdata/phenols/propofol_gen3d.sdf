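propofol
 OpenBabel09282620383D

 31 31  0  0  0  0  0  0  0  0999 V2000
    3.5809    0.3872   -1.1202 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.5965    0.0812    0.0092 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.1571    0.0641   -0.5257 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.9853   -1.1934    0.7503 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.5405   -2.4489    0.3144 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.8380   -3.6021    1.0381 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.5987   -3.5267    2.1991 C   0  0  0  0  0  0  0  0  0  0  0  0
    4.1104   -2.3015    2.6526 C   0  0  0  0  0  0  0  0  0  0  0  0
    4.9431   -2.2418    3.9293 C   0  0  0  0  0  0  0  0  0  0  0  0
    4.0278   -2.0188    5.1370 C   0  0  0  0  0  0  0  0  0  0  0  0
    5.8303   -3.4710    4.1768 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.7866   -1.1446    1.9090 C   0  0  0  0  0  0  0  0  0  0  0  0
    4.2393    0.0898    2.2958 O   0  0  0  0  0  0  0  0  0  0  0  0
    3.2846    1.2974   -1.6545 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.6292   -0.4300   -1.8467 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.5907    0.5487   -0.7278 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.6287    0.9199    0.7174 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.0176   -0.6791   -1.3177 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.8945    1.0391   -0.9479 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.4451   -0.1558    0.2774 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.9445   -2.5480   -0.5885 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.4613   -4.5642    0.6965 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.7841   -4.4488    2.7434 H   0  0  0  0  0  0  0  0  0  0  0  0
    5.6341   -1.3920    3.8534 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.2868   -2.8215    5.2292 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.4810   -1.0742    5.0530 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.6067   -1.9868    6.0664 H   0  0  0  0  0  0  0  0  0  0  0  0
    5.2410   -4.3717    4.3884 H   0  0  0  0  0  0  0  0  0  0  0  0
    6.4775   -3.3054    5.0454 H   0  0  0  0  0  0  0  0  0  0  0  0
    6.4737   -3.6753    3.3147 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.2276    0.1225    3.2648 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  1 14  1  0  0  0  0
  1 15  1  0  0  0  0
  1 16  1  0  0  0  0
  2  3  1  0  0  0  0
  2  4  1  0  0  0  0
  2 17  1  0  0  0  0
  3 18  1  0  0  0  0
  3 19  1  0  0  0  0
  3 20  1  0  0  0  0
  4  5  1  0  0  0  0
  4 12  2  0  0  0  0
  5  6  2  0  0  0  0
  5 21  1  0  0  0  0
  6  7  1  0  0  0  0
  6 22  1  0  0  0  0
  7  8  2  0  0  0  0
  7 23  1  0  0  0  0
  8  9  1  0  0  0  0
  8 12  1  0  0  0  0
  9 10  1  0  0  0  0
  9 11  1  0  0  0  0
  9 24  1  0  0  0  0
 10 25  1  0  0  0  0
 10 26  1  0  0  0  0
 10 27  1  0  0  0  0
 11 28  1  0  0  0  0
 11 29  1  0  0  0  0
 11 30  1  0  0  0  0
 12 13  1  0  0  0  0
 13 31  1  0  0  0  0
M  END
$$$$
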