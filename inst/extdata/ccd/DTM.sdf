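DTM
  CCD transcription (kekulized bond orders)

 49 51  0  0  0  0  0  0  0  0999 V2000
    1.0520    0.4230    5.3830 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.9370    1.0360    4.3740 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.6110    0.1940    3.2830 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.4520    0.0570    2.1720 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.0500   -0.7930    1.1560 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.1660   -1.4690    1.2630 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.6090   -0.5230    3.3230 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.4240   -1.8660   -1.0490 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.6160   -1.0890   -2.0570 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.7530   -0.9820   -1.9080 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.4990   -0.2680   -2.8330 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.8670    0.3460   -3.9070 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.5090    0.2310   -4.0570 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.2480   -0.4840   -3.1270 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.1900   -0.8850   -1.5010 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.6430    2.3990   -4.3540 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.5250    0.5360   -4.9830 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.1320   -0.2580   -0.0820 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.4030   -0.3740    4.3940 N   0  0  0  0  0  0  0  0  0  0  0  0
    1.9020    0.5470    6.4670 N   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0840    1.1140    5.3840 N   0  0  0  0  0  0  0  0  0  0  0  0
   -2.1120    1.7570    4.3830 N   0  0  0  0  0  0  0  0  0  0  0  0
    0.9450   -1.3240    2.3110 N   0  0  0  0  0  0  0  0  0  0  0  0
   -1.8560   -0.9700    0.0250 N   0  0  0  0  0  0  0  0  0  0  0  0
    2.8470   -0.1630   -2.6850 O   0  0  0  0  0  0  0  0  0  0  0  0
    1.5960    1.0480   -4.8170 O   0  0  0  0  0  0  0  0  0  0  0  0
   -1.1310    0.8260   -5.1090 O   0  0  0  0  0  0  0  0  0  0  0  0
   -2.3860    0.5950    2.1120 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.4750   -2.1280    0.4650 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.2980   -2.2960   -1.5380 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8110   -2.6650   -0.6320 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.2430   -1.4560   -1.0700 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.3190   -0.5700   -3.2410 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.2670   -0.8300   -1.3400 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.6730   -0.4490   -0.6460 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.8930   -1.9280   -1.6120 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.2190    3.0040   -5.0540 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.6290    2.7940   -4.2820 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.1150    2.4310   -3.3720 H   0  0  0  0  0  0  0  0  0  0  0  0
   -3.0680    0.9950   -5.8090 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.6750   -0.5420   -5.0040 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.8950    0.9360   -4.0380 H   0  0  0  0  0  0  0  0  0  0  0  0
   -3.6150   -0.5190   -1.0240 H   0  0  0  0  0  0  0  0  0  0  0  0
   -3.7780   -0.5420    0.7480 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.9520    0.8160   -0.0520 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.6640    1.1280    7.2060 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.7360    0.0530    6.4880 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.3230    2.3300    5.1370 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.7280    1.6900    3.6370 H   0  0  0  0  0  0  0  0  0  0  0  0
  1 19  2  0  0  0  0
  1 20  1  0  0  0  0
  1 21  1  0  0  0  0
  2  3  1  0  0  0  0
  2 21  2  0  0  0  0
  2 22  1  0  0  0  0
  3  4  2  0  0  0  0
  3  7  1  0  0  0  0
  4  5  1  0  0  0  0
  4 28  1  0  0  0  0
  5  6  2  0  0  0  0
  5 24  1  0  0  0  0
  6 23  1  0  0  0  0
  6 29  1  0  0  0  0
  7 19  1  0  0  0  0
  7 23  2  0  0  0  0
  8  9  1  0  0  0  0
  8 24  1  0  0  0  0
  8 30  1  0  0  0  0
  8 31  1  0  0  0  0
  9 10  2  0  0  0  0
  9 14  1  0  0  0  0
 10 11  1  0  0  0  0
 10 32  1  0  0  0  0
 11 12  2  0  0  0  0
 11 25  1  0  0  0  0
 12 13  1  0  0  0  0
 12 26  1  0  0  0  0
 13 14  2  0  0  0  0
 13 27  1  0  0  0  0
 14 33  1  0  0  0  0
 15 25  1  0  0  0  0
 15 34  1  0  0  0  0
 15 35  1  0  0  0  0
 15 36  1  0  0  0  0
 16 26  1  0  0  0  0
 16 37  1  0  0  0  0
 16 38  1  0  0  0  0
 16 39  1  0  0  0  0
 17 27  1  0  0  0  0
 17 40  1  0  0  0  0
 17 41  1  0  0  0  0
 17 42  1  0  0  0  0
 18 24  1  0  0  0  0
 18 43  1  0  0  0  0
 18 44  1  0  0  0  0
 18 45  1  0  0  0  0
 20 46  1  0  0  0  0
 20 47  1  0  0  0  0
 22 48  1  0  0  0  0
 22 49  1  0  0  0  0
M  END
$$$$
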