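MTX
  CCD transcription (kekulized bond orders)

 55 57  0  0  0  0  0  0  0  0999 V2000
    2.3950    0.5590    5.4700 N   0  0  0  0  0  0  0  0  0  0  0  0
    2.3100    0.2090    6.7380 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.4810    0.0800    7.4610 N   0  0  0  0  0  0  0  0  0  0  0  0
    1.1580   -0.0240    7.3590 N   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000    0.0810    6.7230 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.1920   -0.1610    7.3690 N   0  0  0  0  0  0  0  0  0  0  0  0
    0.0310    0.4670    5.3110 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.0770    0.6040    4.5910 N   0  0  0  0  0  0  0  0  0  0  0  0
   -0.9890    0.9480    3.3240 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.2530    1.1790    2.7350 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.3630    1.0540    3.4310 N   0  0  0  0  0  0  0  0  0  0  0  0
    1.2970    0.7010    4.7170 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.2440    1.0990    2.5030 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.5740   -0.1820    1.8750 N   0  0  0  0  0  0  0  0  0  0  0  0
   -3.4380   -1.1380    2.5720 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.0560   -1.1070   -1.8870 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.8810   -2.0190   -1.2210 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.3810   -1.7100    0.0220 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.0670   -0.4910    0.6180 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.2500    0.4200   -0.0450 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.7420    0.1140   -1.2860 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.5180   -1.4360   -3.2210 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.7920   -2.5000   -3.7420 O   0  0  0  0  0  0  0  0  0  0  0  0
    0.2760   -0.5560   -3.8620 N   0  0  0  0  0  0  0  0  0  0  0  0
    0.8110   -0.8820   -5.1860 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.1350   -1.5840   -5.0340 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.4890   -2.3920   -5.8610 O   0  0  0  0  0  0  0  0  0  0  0  0
    2.9220   -1.3130   -3.9810 O   0  0  0  0  0  0  0  0  0  0  0  0
    1.0050    0.4050   -5.9890 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.3390    1.1180   -6.1430 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.1480    2.3860   -6.9330 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.9510    2.6890   -7.3330 O   0  0  0  0  0  0  0  0  0  0  0  0
   -1.1980    3.1800   -7.1940 O   0  0  0  0  0  0  0  0  0  0  0  0
    3.4480   -0.1750    8.3960 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.3350    0.2460    7.0330 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.1930   -0.4150    8.3050 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.0300   -0.0780    6.8870 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.3050    1.4640    1.6950 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.0840    1.8510    1.7310 H   0  0  0  0  0  0  0  0  0  0  0  0
   -3.0650    1.4090    3.1490 H   0  0  0  0  0  0  0  0  0  0  0  0
   -3.7350   -0.7240    3.5350 H   0  0  0  0  0  0  0  0  0  0  0  0
   -4.3260   -1.3310    1.9700 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.8960   -2.0710    2.7290 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.1250   -2.9640   -1.6820 H   0  0  0  0  0  0  0  0  0  0  0  0
   -3.0180   -2.4130    0.5380 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.0080    1.3640    0.4190 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.1050    0.8200   -1.7980 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.4940    0.2920   -3.4460 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.1120   -1.5350   -5.7100 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.7720   -1.7630   -3.8840 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.7040    1.0570   -5.4650 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.4030    0.1620   -6.9740 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.0380    0.4650   -6.6660 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.7370    1.3600   -5.1570 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.0750    3.9940   -7.7010 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  2  0  0  0  0
  1 12  1  0  0  0  0
  2  3  1  0  0  0  0
  2  4  1  0  0  0  0
  3 34  1  0  0  0  0
  3 35  1  0  0  0  0
  4  5  2  0  0  0  0
  5  6  1  0  0  0  0
  5  7  1  0  0  0  0
  6 36  1  0  0  0  0
  6 37  1  0  0  0  0
  7  8  1  0  0  0  0
  7 12  2  0  0  0  0
  8  9  2  0  0  0  0
  9 10  1  0  0  0  0
  9 13  1  0  0  0  0
 10 11  2  0  0  0  0
 10 38  1  0  0  0  0
 11 12  1  0  0  0  0
 13 14  1  0  0  0  0
 13 39  1  0  0  0  0
 13 40  1  0  0  0  0
 14 15  1  0  0  0  0
 14 19  1  0  0  0  0
 15 41  1  0  0  0  0
 15 42  1  0  0  0  0
 15 43  1  0  0  0  0
 16 17  2  0  0  0  0
 16 21  1  0  0  0  0
 16 22  1  0  0  0  0
 17 18  1  0  0  0  0
 17 44  1  0  0  0  0
 18 19  2  0  0  0  0
 18 45  1  0  0  0  0
 19 20  1  0  0  0  0
 20 21  2  0  0  0  0
 20 46  1  0  0  0  0
 21 47  1  0  0  0  0
 22 23  2  0  0  0  0
 22 24  1  0  0  0  0
 24 25  1  0  0  0  0
 24 48  1  0  0  0  0
 25 26  1  0  0  0  0
 25 29  1  0  0  0  0
 25 49  1  0  0  0  0
 26 27  2  0  0  0  0
 26 28  1  0  0  0  0
 28 50  1  0  0  0  0
 29 30  1  0  0  0  0
 29 51  1  0  0  0  0
 29 52  1  0  0  0  0
 30 31  1  0  0  0  0
 30 53  1  0  0  0  0
 30 54  1  0  0  0  0
 31 32  2  0  0  0  0
 31 33  1  0  0  0  0
 33 55  1  0  0  0  0
M  END
$$$$
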