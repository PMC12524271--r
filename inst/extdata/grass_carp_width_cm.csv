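size_class,fish,real,p1,p2,p3,m1,m2,m3
L,1,4.17,4.41,4.08,4.27,0.24,0.09,0.10
L,2,4.03,4.1,3.82,3.8,0.07,0.21,0.23
L,3,3.90,3.8,3.89,3.84,0.1,0.01,0.06
L,4,4.18,4.15,3.98,4.4,0.03,0.20,0.22
L,5,4.36,4.23,4.36,4.31,0.13,0,0.05
M-L,6,3.397,3.32,3.53,3.3,0.08,0.13,0.10
M-L,7,3.13,3.01,3.26,3.02,0.12,0.13,0.11
M-L,8,3.10,3.23,3.03,3.17,0.13,0.07,0.08
M-L,9,3.09,2.96,3.14,3.03,0.13,0.05,0.06
M-L,10,3.42,3.53,3.6,3.37,0.11,0.18,0.05
M-S,11,3.0,2.77,2.95,2.9,0.23,0.05,0.10
M-S,12,2.85,2.66,2.75,2.91,0.19,0.10,0.06
M-S,13,2.68,2.7,2.62,2.5,0.02,0.06,0.18
M-S,14,2.54,2.54,2.49,2.38,0,0.05,0.16
M-S,15,2.49,2.49,2.58,2.56,0,0.09,0.07
S,16,1.93,1.87,1.86,1.8,0.06,0.07,0.13
S,17,1.87,1.82,1.91,1.74,0.05,0.04,0.13
S,18,1.95,1.92,2.01,1.89,0.03,0.06,0.06
S,19,1.91,1.78,1.89,1.91,0.13,0.02,0
S,20,1.98,1.87,1.83,2.15,0.11,0.15,0.17
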