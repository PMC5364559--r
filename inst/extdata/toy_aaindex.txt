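H TOYI000001
D toy hydropathy-like index (synthetic fixture)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
   1.800  -4.500  -3.500  -3.500   2.500  -3.500  -3.500  -0.400  -3.200   4.500
   3.800  -3.900   1.900   2.800  -1.600  -0.800  -0.700  -0.900  -1.300   4.200
//
H TOYI000002
D toy volume-like index (synthetic fixture)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
  88.600 173.400 114.100 111.100 108.500 143.800 138.400  60.100 153.200 166.700
 166.700 168.600 162.900 189.900 112.700  89.000 116.100 227.800 193.600 140.000
//
H TOYI000003
D toy index with missing values (synthetic fixture)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
   0.100      NA   0.300   0.400   0.500   0.600   0.700   0.800   0.900   1.000
   1.100   1.200      NA   1.400   1.500   1.600   1.700   1.800   1.900   2.000
//
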