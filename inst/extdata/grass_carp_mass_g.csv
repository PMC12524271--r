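size_class,fish,real,p1,p2,p3,m1,m2,m3
L,1,106.6,113.5,108.3,107.6,6.9,1.7,1.0
L,2,95.7,105.5,89.4,87.5,9.8,6.3,8.2
L,3,90.6,92.0,93.5,93.1,1.4,2.9,2.5
L,4,103.2,108.6,94.4,111.5,5.4,8.8,8.3
L,5,124.3,117.5,116.7,120.1,6.8,7.6,4.2
M-L,6,65.6,64.2,66.4,62.6,1.4,0.8,3.0
M-L,7,44.5,42.8,49.3,44.9,1.7,4.8,0.4
M-L,8,49.9,53.2,47.3,49.7,3.3,2.6,0.2
M-L,9,42.6,35.0,45.4,38.7,7.6,2.8,3.9
M-L,10,65.3,67.8,72.0,63.5,2.5,6.7,1.8
M-S,11,35.3,32.9,35.0,34.5,2.4,0.3,0.8
M-S,12,34.8,31.7,37.2,34.5,3.1,2.4,0.3
M-S,13,24.8,27.6,29.0,22.5,2.8,4.2,2.3
M-S,14,19.8,21.1,20.8,20.0,1.3,1.0,0.2
M-S,15,25.4,24.4,27.9,25.5,1.0,2.5,0.1
S,16,10.7,11.2,11.1,9.7,0.5,0.4,1.0
S,17,9.9,9.2,11.3,8.4,0.7,1.4,1.5
S,18,12.1,11.7,12.3,11.4,0.4,0.2,0.7
S,19,12.1,9.9,11.4,11.3,2.2,0.7,0.8
S,20,12.7,11.1,10.9,13.0,1.6,1.8,0.3
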