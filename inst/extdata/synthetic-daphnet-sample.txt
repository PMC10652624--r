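0 23 -15 993 0 0 0 0 0 0 0
16 14 26 1018 0 0 0 0 0 0 0
31 45 25 1000 0 0 0 0 0 0 0
47 72 54 1002 0 0 0 0 0 0 0
62 88 67 992 0 0 0 0 0 0 1
78 106 73 985 0 0 0 0 0 0 1
94 138 90 1028 0 0 0 0 0 0 1
109 141 77 1010 0 0 0 0 0 0 1
125 150 93 1009 0 0 0 0 0 0 1
141 172 99 1005 0 0 0 0 0 0 1
156 151 91 994 0 0 0 0 0 0 1
172 167 94 1000 0 0 0 0 0 0 1
188 151 62 991 0 0 0 0 0 0 1
203 115 59 1013 0 0 0 0 0 0 1
219 112 57 1008 0 0 0 0 0 0 1
234 75 44 1003 0 0 0 0 0 0 1
250 37 33 998 0 0 0 0 0 0 1
266 17 12 989 0 0 0 0 0 0 1
281 -6 -12 1001 0 0 0 0 0 0 1
297 -22 -14 1025 0 0 0 0 0 0 1
312 -49 -31 1009 0 0 0 0 0 0 1
328 -74 -60 1007 0 0 0 0 0 0 1
344 -89 -65 1014 0 0 0 0 0 0 1
359 -133 -61 1013 0 0 0 0 0 0 1
375 -121 -89 1021 0 0 0 0 0 0 1
391 -142 -88 1007 0 0 0 0 0 0 1
406 -141 -83 985 0 0 0 0 0 0 1
422 -144 -98 994 0 0 0 0 0 0 1
438 -156 -103 1001 0 0 0 0 0 0 1
453 -140 -71 995 0 0 0 0 0 0 1
469 -133 -63 1002 0 0 0 0 0 0 1
484 -101 -65 1004 0 0 0 0 0 0 1
500 -87 -49 998 0 0 0 0 0 0 1
516 -66 -38 1010 0 0 0 0 0 0 1
531 -45 -24 993 0 0 0 0 0 0 1
547 -20 -1 1016 0 0 0 0 0 0 1
562 22 17 989 0 0 0 0 0 0 1
578 27 20 1000 0 0 0 0 0 0 1
594 61 41 981 0 0 0 0 0 0 1
609 89 58 1000 0 0 0 0 0 0 1
625 118 67 998 0 0 0 0 0 0 1
641 116 55 991 0 0 0 0 0 0 1
656 133 58 978 0 0 0 0 0 0 1
672 132 92 994 0 0 0 0 0 0 1
688 146 102 1005 0 0 0 0 0 0 1
703 145 77 997 0 0 0 0 0 0 1
719 158 93 1001 0 0 0 0 0 0 1
734 141 84 996 0 0 0 0 0 0 1
750 122 80 996 0 0 0 0 0 0 1
766 113 76 988 0 0 0 0 0 0 1
781 81 51 1017 0 0 0 0 0 0 1
797 60 30 997 0 0 0 0 0 0 1
812 39 43 990 0 0 0 0 0 0 1
828 26 29 1011 0 0 0 0 0 0 1
844 -10 1 1010 0 0 0 0 0 0 1
859 -39 -28 1013 0 0 0 0 0 0 1
875 -84 -36 1018 0 0 0 0 0 0 1
891 -87 -60 973 0 0 0 0 0 0 1
906 -108 -56 1007 0 0 0 0 0 0 1
922 -135 -72 1012 0 0 0 0 0 0 1
938 -138 -101 1004 0 0 0 0 0 0 1
953 -145 -95 988 0 0 0 0 0 0 1
969 -144 -109 996 0 0 0 0 0 0 1
984 -142 -77 985 0 0 0 0 0 0 1
1000 3 -3 989 0 0 0 0 0 0 2
1016 -51 -60 993 0 0 0 0 0 0 2
1031 -98 -86 1023 0 0 0 0 0 0 2
1047 -108 -92 1001 0 0 0 0 0 0 2
1062 -87 -89 1008 0 0 0 0 0 0 2
1078 -44 -42 994 0 0 0 0 0 0 2
1094 16 4 1002 0 0 0 0 0 0 2
1109 62 64 994 0 0 0 0 0 0 2
1125 105 109 990 0 0 0 0 0 0 2
1141 110 104 994 0 0 0 0 0 0 2
1156 76 74 1007 0 0 0 0 0 0 2
1172 27 38 997 0 0 0 0 0 0 2
1188 -32 -7 1009 0 0 0 0 0 0 2
1203 -86 -76 1002 0 0 0 0 0 0 2
1219 -115 -98 999 0 0 0 0 0 0 2
1234 -92 -89 991 0 0 0 0 0 0 2
1250 -81 -82 989 0 0 0 0 0 0 2
1266 -29 -11 1010 0 0 0 0 0 0 2
1281 35 28 1001 0 0 0 0 0 0 2
1297 85 55 1011 0 0 0 0 0 0 2
1312 110 88 991 0 0 0 0 0 0 2
1328 110 85 989 0 0 0 0 0 0 2
1344 73 52 984 0 0 0 0 0 0 2
1359 15 29 984 0 0 0 0 0 0 2
1375 -64 -38 992 0 0 0 0 0 0 2
1391 -91 -76 1011 0 0 0 0 0 0 2
1406 -103 -106 1012 0 0 0 0 0 0 2
1422 -115 -91 1002 0 0 0 0 0 0 2
1438 -60 -55 1001 0 0 0 0 0 0 2
1453 -4 -17 1006 0 0 0 0 0 0 2
1469 65 55 1005 0 0 0 0 0 0 2
1484 97 87 999 0 0 0 0 0 0 2
1500 131 90 986 0 0 0 0 0 0 2
1516 88 95 1008 0 0 0 0 0 0 2
1531 52 45 997 0 0 0 0 0 0 2
1547 -7 -13 996 0 0 0 0 0 0 2
1562 -61 -57 995 0 0 0 0 0 0 2
1578 -103 -106 981 0 0 0 0 0 0 2
1594 -120 -86 990 0 0 0 0 0 0 2
1609 -108 -82 1023 0 0 0 0 0 0 2
1625 -43 -37 1002 0 0 0 0 0 0 2
1641 2 11 977 0 0 0 0 0 0 2
1656 86 76 999 0 0 0 0 0 0 2
1672 123 76 1001 0 0 0 0 0 0 2
1688 126 94 1007 0 0 0 0 0 0 2
1703 90 71 994 0 0 0 0 0 0 2
1719 31 28 1003 0 0 0 0 0 0 2
1734 -25 -28 1006 0 0 0 0 0 0 2
1750 -78 -72 1021 0 0 0 0 0 0 2
1766 -110 -92 1009 0 0 0 0 0 0 2
1781 -124 -102 984 0 0 0 0 0 0 2
1797 -65 -49 1010 0 0 0 0 0 0 2
1812 -36 -22 1005 0 0 0 0 0 0 2
1828 51 52 997 0 0 0 0 0 0 2
1844 103 68 1008 0 0 0 0 0 0 2
1859 122 94 990 0 0 0 0 0 0 2
1875 95 70 1005 0 0 0 0 0 0 2
1891 87 65 1003 0 0 0 0 0 0 2
1906 19 -5 1009 0 0 0 0 0 0 2
1922 -53 -71 983 0 0 0 0 0 0 2
1938 -92 -93 985 0 0 0 0 0 0 2
1953 -105 -99 1022 0 0 0 0 0 0 2
1969 -101 -89 1004 0 0 0 0 0 0 2
1984 -61 -55 1007 0 0 0 0 0 0 2
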