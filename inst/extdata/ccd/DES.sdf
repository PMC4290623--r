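DES
  CCD transcription (kekulized bond orders)

 40 41  0  0  0  0  0  0  0  0999 V2000
    2.3520    0.9940    0.9590 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.9400   -0.2300    0.1400 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.5680   -0.0070   -0.4410 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.3760   -0.0240   -1.9020 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0590    1.1550   -2.5810 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.1190    1.1340   -3.9470 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0140   -0.0560   -4.6490 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.1630   -0.0710   -5.9960 O   0  0  0  0  0  0  0  0  0  0  0  0
    0.3280   -1.2310   -3.9790 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.5150   -1.2190   -2.6130 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.4780    0.2060    0.3710 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.3160    0.0800    1.8300 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.5680    1.1760    2.6610 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.4150    1.0530    4.0250 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0110   -0.1560    4.5740 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.1370   -0.2730    5.9200 O   0  0  0  0  0  0  0  0  0  0  0  0
    0.2400   -1.2480    3.7530 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0840   -1.1360    2.3880 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.8190    0.5750   -0.2080 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.6670   -0.6860   -0.3780 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.6360    1.1490    1.7660 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.3450    0.8330    1.3790 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.3690    1.8730    0.3140 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.6560   -0.3850   -0.6660 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.9230   -1.1090    0.7840 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0440    2.0820   -2.0360 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.3640    2.0450   -4.4730 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.7020    0.0970   -6.3940 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.4300   -2.1550   -4.5290 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.7590   -2.1330   -2.0930 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8820    2.1170    2.2340 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.6100    1.8990    4.6670 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.7170   -0.5580    6.2720 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.5540   -2.1860    4.1850 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.2790   -1.9850    1.7500 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.3280    1.2670    0.4630 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.6770    1.0500   -1.1790 H   0  0  0  0  0  0  0  0  0  0  0  0
   -3.6490   -0.4150   -0.7650 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.1750   -1.3630   -1.0760 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.7810   -1.1790    0.5870 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  1 21  1  0  0  0  0
  1 22  1  0  0  0  0
  1 23  1  0  0  0  0
  2  3  1  0  0  0  0
  2 24  1  0  0  0  0
  2 25  1  0  0  0  0
  3  4  1  0  0  0  0
  3 11  2  0  0  0  0
  4  5  1  0  0  0  0
  4 10  2  0  0  0  0
  5  6  2  0  0  0  0
  5 26  1  0  0  0  0
  6  7  1  0  0  0  0
  6 27  1  0  0  0  0
  7  8  1  0  0  0  0
  7  9  2  0  0  0  0
  8 28  1  0  0  0  0
  9 10  1  0  0  0  0
  9 29  1  0  0  0  0
 10 30  1  0  0  0  0
 11 12  1  0  0  0  0
 11 19  1  0  0  0  0
 12 13  1  0  0  0  0
 12 18  2  0  0  0  0
 13 14  2  0  0  0  0
 13 31  1  0  0  0  0
 14 15  1  0  0  0  0
 14 32  1  0  0  0  0
 15 16  1  0  0  0  0
 15 17  2  0  0  0  0
 16 33  1  0  0  0  0
 17 18  1  0  0  0  0
 17 34  1  0  0  0  0
 18 35  1  0  0  0  0
 19 20  1  0  0  0  0
 19 36  1  0  0  0  0
 19 37  1  0  0  0  0
 20 38  1  0  0  0  0
 20 39  1  0  0  0  0
 20 40  1  0  0  0  0
M  END
$$$$
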