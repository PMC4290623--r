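RAL
  CCD transcription (kekulized bond orders)

 61 65  0  0  0  0  0  0  0  0999 V2000
    2.4440    0.8250   -3.6100 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.4780    0.3980   -4.4010 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.3480   -0.7220   -5.2150 C   0  0  0  0  0  0  0  0  0  0  0  0
    4.3850   -1.1290   -5.9940 O   0  0  0  0  0  0  0  0  0  0  0  0
    2.1500   -1.4190   -5.2250 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.1060   -0.9940   -4.4300 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.5420   -1.5900   -4.1610 S   0  0  0  0  0  0  0  0  0  0  0  0
   -1.0960   -0.3820   -2.9750 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.4110   -0.2840   -2.3140 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.9690   -1.4060   -1.6940 C   0  0  0  0  0  0  0  0  0  0  0  0
   -4.1970   -1.3100   -1.0780 C   0  0  0  0  0  0  0  0  0  0  0  0
   -4.8810   -0.1000   -1.0730 C   0  0  0  0  0  0  0  0  0  0  0  0
   -6.0920   -0.0100   -0.4640 O   0  0  0  0  0  0  0  0  0  0  0  0
   -4.3330    1.0150   -1.6930 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.1030    0.9300   -2.3070 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.2110    0.1350   -3.5980 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0050    0.4490   -2.8260 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0330    1.6000   -1.9230 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.3920    2.6870   -2.3380 O   0  0  0  0  0  0  0  0  0  0  0  0
    0.3620    1.4420   -0.5090 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.4310    2.5590    0.3260 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.8000    2.4080    1.6450 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.1030    1.1470    2.1430 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.0340    0.0330    1.3150 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.6610    0.1750   -0.0020 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.4660    1.0020    3.4430 O   0  0  0  0  0  0  0  0  0  0  0  0
    1.8280   -0.3680    3.6210 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.3080   -0.5870    5.0570 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.2300   -0.2400    5.9920 N   0  0  0  0  0  0  0  0  0  0  0  0
    1.7520   -0.4710    7.3430 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.6770   -0.1370    8.3780 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.5300   -1.0550    8.1650 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.0120   -0.9150    6.7180 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.1510   -1.2090    5.7690 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.5730    1.6980   -2.9870 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.4110    0.9420   -4.3930 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.2920   -0.6770   -6.8430 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.0350   -2.2910   -5.8510 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.4370   -2.3460   -1.6970 H   0  0  0  0  0  0  0  0  0  0  0  0
   -4.6280   -2.1760   -0.5980 H   0  0  0  0  0  0  0  0  0  0  0  0
   -5.9220    0.1630    0.4710 H   0  0  0  0  0  0  0  0  0  0  0  0
   -4.8690    1.9530   -1.6870 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.6760    1.7990   -2.7840 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.1970    3.5400   -0.0600 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.8540    3.2710    2.2920 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.2700   -0.9450    1.7060 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.6080   -0.6900   -0.6460 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.9620   -1.0000    3.4270 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.6290   -0.6250    2.9270 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.5840   -1.6330    5.1920 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.1750    0.0450    5.2510 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.0420   -1.5170    7.4450 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.6240    0.1620    7.5070 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.0770   -0.2870    9.3810 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.3690    0.9020    8.2600 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.2390   -2.0890    8.3550 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.3310   -0.7690    8.8460 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.8200   -1.6230    6.5330 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.3710    0.0990    6.5500 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.1940   -1.1360    4.7380 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.5250   -2.2160    5.9550 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  2  0  0  0  0
  1 16  1  0  0  0  0
  1 35  1  0  0  0  0
  2  3  1  0  0  0  0
  2 36  1  0  0  0  0
  3  4  1  0  0  0  0
  3  5  2  0  0  0  0
  4 37  1  0  0  0  0
  5  6  1  0  0  0  0
  5 38  1  0  0  0  0
  6  7  1  0  0  0  0
  6 16  2  0  0  0  0
  7  8  1  0  0  0  0
  8  9  1  0  0  0  0
  8 17  2  0  0  0  0
  9 10  1  0  0  0  0
  9 15  2  0  0  0  0
 10 11  2  0  0  0  0
 10 39  1  0  0  0  0
 11 12  1  0  0  0  0
 11 40  1  0  0  0  0
 12 13  1  0  0  0  0
 12 14  2  0  0  0  0
 13 41  1  0  0  0  0
 14 15  1  0  0  0  0
 14 42  1  0  0  0  0
 15 43  1  0  0  0  0
 16 17  1  0  0  0  0
 17 18  1  0  0  0  0
 18 19  2  0  0  0  0
 18 20  1  0  0  0  0
 20 21  2  0  0  0  0
 20 25  1  0  0  0  0
 21 22  1  0  0  0  0
 21 44  1  0  0  0  0
 22 23  2  0  0  0  0
 22 45  1  0  0  0  0
 23 24  1  0  0  0  0
 23 26  1  0  0  0  0
 24 25  2  0  0  0  0
 24 46  1  0  0  0  0
 25 47  1  0  0  0  0
 26 27  1  0  0  0  0
 27 28  1  0  0  0  0
 27 48  1  0  0  0  0
 27 49  1  0  0  0  0
 28 29  1  0  0  0  0
 28 50  1  0  0  0  0
 28 51  1  0  0  0  0
 29 30  1  0  0  0  0
 29 34  1  0  0  0  0
 30 31  1  0  0  0  0
 30 52  1  0  0  0  0
 30 53  1  0  0  0  0
 31 32  1  0  0  0  0
 31 54  1  0  0  0  0
 31 55  1  0  0  0  0
 32 33  1  0  0  0  0
 32 56  1  0  0  0  0
 32 57  1  0  0  0  0
 33 34  1  0  0  0  0
 33 58  1  0  0  0  0
 33 59  1  0  0  0  0
 34 60  1  0  0  0  0
 34 61  1  0  0  0  0
M  END
$$$$
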