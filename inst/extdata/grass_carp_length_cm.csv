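size_class,fish,real,p1,p2,p3,m1,m2,m3
L,1,17.65,18.2,18.47,18.03,0.55,0.82,0.38
L,2,16.98,17.95,17.83,17.37,0.97,0.85,0.39
L,3,17.71,18.59,17.69,17.9,0.88,0.02,0.19
L,4,17.26,18.08,17.83,17.63,0.82,0.57,0.37
L,5,18.53,18.92,18.42,19.14,0.39,0.11,0.61
M-L,6,15.46,15.67,14.95,15.59,0.21,0.51,0.13
M-L,7,13.30,13.13,13.57,13.84,0.17,0.27,0.54
M-L,8,14.56,14.91,14.15,14.3,0.35,0.41,0.26
M-L,9,13.15,12.79,13.55,12.72,0.36,0.4,0.43
M-L,10,15.40,15.58,15.38,15.53,0.18,0.02,0.13
M-S,11,11.85,12.56,12.65,12.76,0.71,0.8,0.92
M-S,12,12.35,12.44,13.17,12.77,0.09,0.82,0.42
M-S,13,11.02,11.05,11.66,10.86,0.03,0.64,0.16
M-S,14,10.03,10.53,10.39,10.4,0.50,0.36,0.37
M-S,15,11.31,11.46,11.98,11.38,0.15,0.67,0.07
S,16,8.66,8.55,9.0,8.45,0.11,0.34,0.21
S,17,8.17,8.13,8.62,8.11,0.04,0.45,0.06
S,18,9.01,9.21,9.17,9.07,0.20,0.16,0.06
S,19,8.86,8.87,9.06,9.11,0.01,0.20,0.25
S,20,9.01,9.08,8.92,8.99,0.07,0.09,0.02
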