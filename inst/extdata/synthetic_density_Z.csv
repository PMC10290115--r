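"z_nm","rho"
-3,0.062854
-2.9,0.072682
-2.8,0.088096
-2.7,0.110901
-2.6,0.142666
-2.5,0.184205
-2.4,0.235001
-2.3,0.292733
-2.2,0.353137
-2.1,0.410332
-2,0.45768
-1.9,0.489025
-1.8,0.5
-1.7,0.489025
-1.6,0.45768
-1.5,0.410332
-1.4,0.353137
-1.3,0.292733
-1.2,0.235001
-1.1,0.184205
-1,0.142666
-0.9,0.110901
-0.8,0.088096
-0.7,0.072682
-0.6,0.062854
-0.5,0.056934
-0.4,0.05356
-0.3,0.05174
-0.2,0.050809
-0.0999999999999996,0.050358
0,0.050151
0.1,0.050358
0.2,0.050809
0.3,0.05174
0.4,0.05356
0.5,0.056934
0.6,0.062854
0.7,0.072682
0.8,0.088096
0.9,0.110901
1,0.142666
1.1,0.184205
1.2,0.235001
1.3,0.292733
1.4,0.353137
1.5,0.410332
1.6,0.45768
1.7,0.489025
1.8,0.5
1.9,0.489025
2,0.45768
2.1,0.410332
2.2,0.353137
2.3,0.292733
2.4,0.235001
2.5,0.184205
2.6,0.142666
2.7,0.110901
2.8,0.088096
2.9,0.072682
3,0.062854
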