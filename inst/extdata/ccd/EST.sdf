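EST
  CCD transcription (kekulized bond orders)

 44 47  0  0  0  0  0  0  0  0999 V2000
    1.4630   -0.4460   -2.4860 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.4540   -0.1540   -3.8330 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.2700    0.2320   -4.4440 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.2490    0.5180   -5.7720 O   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8880    0.3280   -3.6940 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8770    0.0390   -2.3360 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.1740    0.1760   -1.5820 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.1020   -0.5200   -0.2230 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8160   -0.0770    0.4740 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.3660   -0.7020   -0.2760 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.2790   -0.3550   -1.7330 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.6950   -0.2820    0.3320 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.7440   -0.6400    1.8300 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.5700    0.0410    2.5040 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.7320   -0.5570    1.9060 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.8160   -0.0700    2.8620 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.1150    0.0740    4.2360 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.3960   -0.2410    4.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.2210    0.6110    4.7960 O   0  0  0  0  0  0  0  0  0  0  0  0
    0.6220    1.5500    2.2550 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.3840   -0.7500   -2.0110 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.3640   -0.2270   -4.4100 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.4380    1.4620   -5.8590 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.8100    0.6290   -4.1690 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.9770   -0.2680   -2.1690 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.3880    1.2340   -1.4290 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.0900   -1.6010   -0.3650 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.9640   -0.2380    0.3800 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.7380    1.0090    0.4450 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.2840   -1.7850   -0.1850 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.8190    0.7940    0.2160 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.5060   -0.7940   -0.1850 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.6780   -0.2840    2.2650 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.6660   -1.7200    1.9550 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.6830   -1.6460    1.9280 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.2050    0.8920    2.5320 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.6210   -0.8020    2.9250 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.2230    1.0940    4.6050 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.5410   -0.6290    4.9500 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.6090   -1.2890    4.2120 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.0020    0.4280    5.7200 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.6800    1.7390    1.1830 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.2760    2.0160    2.6580 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.5000    1.9690    2.7460 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  2  0  0  0  0
  1 11  1  0  0  0  0
  1 21  1  0  0  0  0
  2  3  1  0  0  0  0
  2 22  1  0  0  0  0
  3  4  1  0  0  0  0
  3  5  2  0  0  0  0
  4 23  1  0  0  0  0
  5  6  1  0  0  0  0
  5 24  1  0  0  0  0
  6  7  1  0  0  0  0
  6 11  2  0  0  0  0
  7  8  1  0  0  0  0
  7 25  1  0  0  0  0
  7 26  1  0  0  0  0
  8  9  1  0  0  0  0
  8 27  1  0  0  0  0
  8 28  1  0  0  0  0
  9 10  1  0  0  0  0
  9 15  1  0  0  0  0
  9 29  1  0  0  0  0
 10 11  1  0  0  0  0
 10 12  1  0  0  0  0
 10 30  1  0  0  0  0
 12 13  1  0  0  0  0
 12 31  1  0  0  0  0
 12 32  1  0  0  0  0
 13 14  1  0  0  0  0
 13 33  1  0  0  0  0
 13 34  1  0  0  0  0
 14 15  1  0  0  0  0
 14 18  1  0  0  0  0
 14 20  1  0  0  0  0
 15 16  1  0  0  0  0
 15 35  1  0  0  0  0
 16 17  1  0  0  0  0
 16 36  1  0  0  0  0
 16 37  1  0  0  0  0
 17 18  1  0  0  0  0
 17 38  1  0  0  0  0
 17 39  1  0  0  0  0
 18 19  1  0  0  0  0
 18 40  1  0  0  0  0
 19 41  1  0  0  0  0
 20 42  1  0  0  0  0
 20 43  1  0  0  0  0
 20 44  1  0  0  0  0
M  END
$$$$
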