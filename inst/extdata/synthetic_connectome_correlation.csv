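reg01,reg02,reg03,reg04,reg05,reg06,reg07,reg08,reg09,reg10,reg11,reg12
1.0000,-0.0500,0.7272,0.1536,-0.4083,-0.3644,0.1633,0.3649,0.5474,-0.1296,0.2570,0.1141
-0.0500,1.0000,0.2349,-0.5574,-0.1155,0.5610,-0.0364,-0.5039,0.0141,0.5281,-0.0552,0.0618
0.7272,0.2349,1.0000,0.0968,-0.4316,0.3039,-0.3733,-0.0101,0.0630,0.4123,0.6351,0.0904
0.1536,-0.5574,0.0968,1.0000,-0.7119,-0.1195,0.0390,0.1023,0.2066,-0.0695,-0.1109,0.6214
-0.4083,-0.1155,-0.4316,-0.7119,1.0000,-0.0728,-0.0211,0.2693,-0.5263,-0.1300,0.2333,-0.8611
-0.3644,0.5610,0.3039,-0.1195,-0.0728,1.0000,-0.3698,-0.3315,-0.6841,0.9335,0.4813,-0.1100
0.1633,-0.0364,-0.3733,0.0390,-0.0211,-0.3698,1.0000,0.6283,0.2663,-0.1034,-0.3246,-0.1328
0.3649,-0.5039,-0.0101,0.1023,0.2693,-0.3315,0.6283,1.0000,-0.1579,-0.0301,0.3866,-0.5768
0.5474,0.0141,0.0630,0.2066,-0.5263,-0.6841,0.2663,-0.1579,1.0000,-0.6383,-0.6550,0.6475
-0.1296,0.5281,0.4123,-0.0695,-0.1300,0.9335,-0.1034,-0.0301,-0.6383,1.0000,0.5906,-0.2092
0.2570,-0.0552,0.6351,-0.1109,0.2333,0.4813,-0.3246,0.3866,-0.6550,0.5906,1.0000,-0.5942
0.1141,0.0618,0.0904,0.6214,-0.8611,-0.1100,-0.1328,-0.5768,0.6475,-0.2092,-0.5942,1.0000
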