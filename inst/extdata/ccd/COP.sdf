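COP
  CCD transcription (kekulized bond orders)

 69 72  0  0  0  0  0  0  0  0999 V2000
    2.1840    0.0370    9.7610 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.6360    0.6200    7.5670 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.4020   -0.0650    7.1770 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.1180   -0.7590    5.6190 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8800   -1.3590    6.6210 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.6310   -0.6730    8.2000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.5790   -0.8320    4.1860 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.9820    0.4670    2.6190 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.7950    1.5610    2.3370 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.3390    1.7120    1.0820 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.0740    0.7640    0.0890 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.2570   -0.3330    0.3750 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7120   -0.4750    1.6310 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.6550    0.9220   -1.2560 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.9770    0.1640   -3.5500 C   0  0  0  0  0  0  0  0  0  0  0  0
   -5.3150   -0.5250   -3.6030 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.0400   -0.4590   -4.5860 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.6810    0.2410   -4.5320 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.7440   -0.3830   -5.5690 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.0680   -0.5960    9.4630 N   0  0  0  0  0  0  0  0  0  0  0  0
    2.5770    0.0850   11.0850 N   0  0  0  0  0  0  0  0  0  0  0  0
    2.9550    0.6290    8.8540 N   0  0  0  0  0  0  0  0  0  0  0  0
    3.4370    1.2340    6.6300 N   0  0  0  0  0  0  0  0  0  0  0  0
    0.9990   -0.1280    5.9130 N   0  0  0  0  0  0  0  0  0  0  0  0
   -0.4980   -1.3070    7.8790 N   0  0  0  0  0  0  0  0  0  0  0  0
   -1.4340    0.3180    3.8880 N   0  0  0  0  0  0  0  0  0  0  0  0
   -3.3990    0.0070   -2.2130 N   0  0  0  0  0  0  0  0  0  0  0  0
   -4.3660    1.8770   -1.5040 O   0  0  0  0  0  0  0  0  0  0  0  0
   -6.1800   -0.1090   -4.3370 O   0  0  0  0  0  0  0  0  0  0  0  0
   -5.5470   -1.6000   -2.8340 O   0  0  0  0  0  0  0  0  0  0  0  0
    0.5560    0.2870   -5.5170 N   0  0  0  0  0  0  0  0  0  0  0  0
    1.5460   -0.0970   -6.3470 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.3590   -1.0010   -7.1380 O   0  0  0  0  0  0  0  0  0  0  0  0
    2.8610    0.5790   -6.2950 C   0  0  0  0  0  0  0  0  0  0  0  0
    4.0360   -0.1700   -6.1030 C   0  0  0  0  0  0  0  0  0  0  0  0
    5.2670    0.4790   -6.0610 C   0  0  0  0  0  0  0  0  0  0  0  0
    5.3280    1.8530   -6.1970 C   0  0  0  0  0  0  0  0  0  0  0  0
    4.1720    2.5910   -6.3800 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.9420    1.9620   -6.4290 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.9660   -1.6390   -5.9580 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.8860   -2.1910   -5.8810 O   0  0  0  0  0  0  0  0  0  0  0  0
    5.0980   -2.3670   -5.9100 O   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7940   -1.8710    6.3610 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.2870   -0.8220    3.5250 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.1420   -1.7530    4.0320 H   0  0  0  0  0  0  0  0  0  0  0  0
   -3.0000    2.2930    3.1050 H   0  0  0  0  0  0  0  0  0  0  0  0
   -3.9700    2.5610    0.8640 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.0510   -1.0670   -0.3890 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.0810   -1.3230    1.8520 H   0  0  0  0  0  0  0  0  0  0  0  0
   -4.1050    1.2240   -3.7680 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.9110   -1.5190   -4.3680 H   0  0  0  0  0  0  0  0  0  0  0  0
   -3.4700   -0.3420   -5.5810 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.8090    1.3010   -4.7510 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.2510    0.1240   -3.5380 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.6160   -1.4430   -5.3510 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.1740   -0.2660   -6.5640 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.3960    0.5410   11.3310 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.0310   -0.3350   11.7680 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.2500    1.6830    6.9070 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.1870    1.2170    5.6920 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.6190    0.9760    4.5760 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.8320   -0.7540   -2.0150 H   0  0  0  0  0  0  0  0  0  0  0  0
   -6.4060   -2.0430   -2.8680 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.7060    1.0090   -4.8860 H   0  0  0  0  0  0  0  0  0  0  0  0
    6.1740   -0.0890   -5.9190 H   0  0  0  0  0  0  0  0  0  0  0  0
    6.2840    2.3540   -6.1600 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.2310    3.6640   -6.4850 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.0430    2.5440   -6.5730 H   0  0  0  0  0  0  0  0  0  0  0  0
    5.0520   -3.3280   -5.8160 H   0  0  0  0  0  0  0  0  0  0  0  0
  1 20  2  0  0  0  0
  1 21  1  0  0  0  0
  1 22  1  0  0  0  0
  2  3  1  0  0  0  0
  2 22  2  0  0  0  0
  2 23  1  0  0  0  0
  3  6  2  0  0  0  0
  3 24  1  0  0  0  0
  4  5  1  0  0  0  0
  4  7  1  0  0  0  0
  4 24  2  0  0  0  0
  5 25  2  0  0  0  0
  5 43  1  0  0  0  0
  6 20  1  0  0  0  0
  6 25  1  0  0  0  0
  7 26  1  0  0  0  0
  7 44  1  0  0  0  0
  7 45  1  0  0  0  0
  8  9  2  0  0  0  0
  8 13  1  0  0  0  0
  8 26  1  0  0  0  0
  9 10  1  0  0  0  0
  9 46  1  0  0  0  0
 10 11  2  0  0  0  0
 10 47  1  0  0  0  0
 11 12  1  0  0  0  0
 11 14  1  0  0  0  0
 12 13  2  0  0  0  0
 12 48  1  0  0  0  0
 13 49  1  0  0  0  0
 14 27  1  0  0  0  0
 14 28  2  0  0  0  0
 15 16  1  0  0  0  0
 15 17  1  0  0  0  0
 15 27  1  0  0  0  0
 15 50  1  0  0  0  0
 16 29  2  0  0  0  0
 16 30  1  0  0  0  0
 17 18  1  0  0  0  0
 17 51  1  0  0  0  0
 17 52  1  0  0  0  0
 18 19  1  0  0  0  0
 18 53  1  0  0  0  0
 18 54  1  0  0  0  0
 19 31  1  0  0  0  0
 19 55  1  0  0  0  0
 19 56  1  0  0  0  0
 21 57  1  0  0  0  0
 21 58  1  0  0  0  0
 23 59  1  0  0  0  0
 23 60  1  0  0  0  0
 26 61  1  0  0  0  0
 27 62  1  0  0  0  0
 30 63  1  0  0  0  0
 31 32  1  0  0  0  0
 31 64  1  0  0  0  0
 32 33  2  0  0  0  0
 32 34  1  0  0  0  0
 34 35  2  0  0  0  0
 34 39  1  0  0  0  0
 35 36  1  0  0  0  0
 35 40  1  0  0  0  0
 36 37  2  0  0  0  0
 36 65  1  0  0  0  0
 37 38  1  0  0  0  0
 37 66  1  0  0  0  0
 38 39  2  0  0  0  0
 38 67  1  0  0  0  0
 39 68  1  0  0  0  0
 40 41  2  0  0  0  0
 40 42  1  0  0  0  0
 42 69  1  0  0  0  0
M  END
$$$$
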