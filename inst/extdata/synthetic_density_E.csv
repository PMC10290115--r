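"z_nm","rho"
-3,0.050103
-2.9,0.050335
-2.8,0.05101
-2.7,0.052802
-2.6,0.057163
-2.5,0.06688
-2.4,0.086658
-2.3,0.12337
-2.2,0.185335
-2.1,0.280066
-2,0.410448
-1.9,0.57045
-1.8,0.742569
-1.7,0.899366
-1.6,1.010005
-1.5,1.05
-1.4,1.010005
-1.3,0.899366
-1.2,0.742569
-1.1,0.57045
-1,0.410448
-0.9,0.280066
-0.8,0.185335
-0.7,0.12337
-0.6,0.086658
-0.5,0.06688
-0.4,0.057163
-0.3,0.052802
-0.2,0.05101
-0.0999999999999996,0.050335
0,0.050103
0.1,0.050335
0.2,0.05101
0.3,0.052802
0.4,0.057163
0.5,0.06688
0.6,0.086658
0.7,0.12337
0.8,0.185335
0.9,0.280066
1,0.410448
1.1,0.57045
1.2,0.742569
1.3,0.899366
1.4,1.010005
1.5,1.05
1.6,1.010005
1.7,0.899366
1.8,0.742569
1.9,0.57045
2,0.410448
2.1,0.280066
2.2,0.185335
2.3,0.12337
2.4,0.086658
2.5,0.06688
2.6,0.057163
2.7,0.052802
2.8,0.05101
2.9,0.050335
3,0.050103
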