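THM
  CCD transcription (kekulized bond orders)

 31 32  0  0  0  0  0  0  0  0999 V2000
    2.2740   -0.7240   -3.7900 O   0  0  0  0  0  0  0  0  0  0  0  0
    1.2080    0.2020   -3.5740 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.1160   -0.4630   -2.7350 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.6000   -0.7600   -1.4060 O   0  0  0  0  0  0  0  0  0  0  0  0
   -1.0550    0.5190   -2.4840 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.9930    0.4810   -3.5620 O   0  0  0  0  0  0  0  0  0  0  0  0
   -1.6810   -0.0460   -1.1860 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.5540   -0.8890   -0.5600 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.2460   -0.3910    0.7820 N   0  0  0  0  0  0  0  0  0  0  0  0
    0.1650    0.8790    0.9430 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.2780    1.6000   -0.0290 O   0  0  0  0  0  0  0  0  0  0  0  0
    0.4540    1.3630    2.1650 N   0  0  0  0  0  0  0  0  0  0  0  0
    0.3290    0.5780    3.2540 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.5900    1.0150    4.3600 O   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0980   -0.7620    3.0990 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.2410   -1.6620    4.2990 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.3820   -1.2220    1.8610 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.9390   -0.2660   -4.3220 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.7920    0.5080   -4.5340 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.5880    1.0770   -3.0470 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.2410   -1.3700   -3.2220 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.6860    1.5320   -2.3280 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.7380    1.0400   -3.3030 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.5420   -0.6730   -1.4200 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.9690    0.7640   -0.5170 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8590   -1.9340   -0.5060 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.7500    2.2810    2.2630 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.0310   -1.1120    5.2000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.2750   -1.9990    4.3780 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.4140   -2.5250    4.1860 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.7130   -2.2400    1.7230 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  1 18  1  0  0  0  0
  2  3  1  0  0  0  0
  2 19  1  0  0  0  0
  2 20  1  0  0  0  0
  3  4  1  0  0  0  0
  3  5  1  0  0  0  0
  3 21  1  0  0  0  0
  4  8  1  0  0  0  0
  5  6  1  0  0  0  0
  5  7  1  0  0  0  0
  5 22  1  0  0  0  0
  6 23  1  0  0  0  0
  7  8  1  0  0  0  0
  7 24  1  0  0  0  0
  7 25  1  0  0  0  0
  8  9  1  0  0  0  0
  8 26  1  0  0  0  0
  9 10  1  0  0  0  0
  9 17  1  0  0  0  0
 10 11  2  0  0  0  0
 10 12  1  0  0  0  0
 12 13  1  0  0  0  0
 12 27  1  0  0  0  0
 13 14  2  0  0  0  0
 13 15  1  0  0  0  0
 15 16  1  0  0  0  0
 15 17  2  0  0  0  0
 16 28  1  0  0  0  0
 16 29  1  0  0  0  0
 16 30  1  0  0  0  0
 17 31  1  0  0  0  0
M  END
$$$$
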