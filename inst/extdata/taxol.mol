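paclitaxel (Taxol)
 OpenBabel09232620182D

 62 68  0  0  1  0  0  0  0  0999 V2000
   -3.4256   -3.7189    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.9095   -2.8624    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.0908   -2.9392    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.1248   -3.1980    0.0000 C   0  0  2  0  0  0  0  0  0  0  0  0
   -0.2588   -2.6980    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.5345   -3.3067    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0000   -1.7321    0.0000 C   0  0  2  0  0  0  0  0  0  0  0  0
    1.0000   -1.7321    0.0000 C   0  0  2  0  0  0  0  0  0  0  0  0
    1.5000   -0.8660    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.0000   -0.0000    0.0000 C   0  0  2  0  0  0  0  0  0  0  0  0
   -0.0000   -0.0000    0.0000 C   0  0  2  0  0  0  0  0  0  0  0  0
   -0.5000   -0.8660    0.0000 C   0  0  1  0  0  0  0  0  0  0  0  0
   -1.4659   -0.6072    0.0000 C   0  0  1  0  0  0  0  0  0  0  0  0
   -2.3320   -1.1072    0.0000 C   0  0  1  0  0  0  0  0  0  0  0  0
   -2.5908   -2.0731    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.5146   -1.6904    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.3841   -2.6819    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.1029   -1.3933    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.3600   -2.1744    0.0000 C   0  0  2  0  0  0  0  0  0  0  0  0
   -4.3514   -2.3049    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
   -4.9602   -1.5116    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -4.5775   -0.5877    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
   -5.9516   -1.6421    0.0000 C   0  0  1  0  0  0  0  0  0  0  0  0
   -6.5604   -0.8487    0.0000 C   0  0  2  0  0  0  0  0  0  0  0  0
   -6.1777    0.0751    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -6.7864    0.8685    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -6.4038    1.7924    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -5.4123    1.9229    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -4.8036    1.1295    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -5.1862    0.2057    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -7.5518   -0.9793    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
   -8.1606   -0.1859    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -7.7779    0.7380    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
   -9.1520   -0.3164    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -9.5347   -1.2403    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
  -10.5261   -1.3708    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
  -11.1349   -0.5775    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
  -10.7522    0.3464    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -9.7608    0.4769    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -6.3343   -2.5660    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
   -2.1192   -0.1301    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
   -1.5965    0.3842    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
   -2.5203    0.7669    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.3137    0.1582    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
   -2.6509    1.7584    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.8575    2.3671    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.9880    3.3586    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.9119    3.7413    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.7053    3.1325    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.5747    2.1411    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000    1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.0000    1.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
   -0.9659   -0.2588    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
   -1.2247   -1.2247    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.5176   -1.9319    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
   -2.1907   -1.4836    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.5000   -2.5981    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
   -0.9239   -1.3494    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.9943   -4.1894    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7877   -4.7982    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.7116   -4.4155    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
   -1.6571   -5.7896    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  2 19  1  0  0  0  0
  2  3  2  0  0  0  0
  3 15  1  0  0  0  0
  3  4  1  0  0  0  0
  4  5  1  0  0  0  0
  4 59  1  6  0  0  0
  5  6  2  0  0  0  0
  5  7  1  0  0  0  0
  7 12  1  0  0  0  0
  7  8  1  0  0  0  0
  7 58  1  6  0  0  0
  8  9  1  0  0  0  0
  8 57  1  6  0  0  0
 10  9  1  6  0  0  0
 10 11  1  0  0  0  0
 10 52  1  0  0  0  0
 11 12  1  0  0  0  0
 11 51  1  0  0  0  0
 11 53  1  1  0  0  0
 12 13  1  0  0  0  0
 13 14  1  0  0  0  0
 13 42  1  0  0  0  0
 14 15  1  0  0  0  0
 14 18  1  0  0  0  0
 14 41  1  0  0  0  0
 15 16  1  0  0  0  0
 15 17  1  0  0  0  0
 18 19  1  0  0  0  0
 19 20  1  0  0  0  0
 20 21  1  0  0  0  0
 21 22  2  0  0  0  0
 21 23  1  0  0  0  0
 23 24  1  0  0  0  0
 23 40  1  0  0  0  0
 24 25  1  0  0  0  0
 24 31  1  0  0  0  0
 25 30  1  0  0  0  0
 25 26  2  0  0  0  0
 26 27  1  0  0  0  0
 27 28  2  0  0  0  0
 28 29  1  0  0  0  0
 29 30  2  0  0  0  0
 31 32  1  0  0  0  0
 32 33  2  0  0  0  0
 32 34  1  0  0  0  0
 34 39  1  0  0  0  0
 34 35  2  0  0  0  0
 35 36  1  0  0  0  0
 36 37  2  0  0  0  0
 37 38  1  0  0  0  0
 38 39  2  0  0  0  0
 42 43  1  0  0  0  0
 43 44  2  0  0  0  0
 43 45  1  0  0  0  0
 45 50  1  0  0  0  0
 45 46  2  0  0  0  0
 46 47  1  0  0  0  0
 47 48  2  0  0  0  0
 48 49  1  0  0  0  0
 49 50  2  0  0  0  0
 51 52  1  0  0  0  0
 53 54  1  0  0  0  0
 54 55  2  0  0  0  0
 54 56  1  0  0  0  0
 59 60  1  0  0  0  0
 60 61  2  0  0  0  0
 60 62  1  0  0  0  0
M  END
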