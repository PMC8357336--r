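case,BC,AIS,BS,CIN1,CIN2,CIN3
1,4,0,5,4,0,0
2,2,5,7,0,0,0
3,0,0,0,0,0,0
4,0,0,9,0,7,3
5,0,0,6,0,0,5
6,0,0,9,0,0,0
7,4,0,3,0,0,0
8,0,0,0,0,0,0
9,3,0,2,0,3,1
10,0,0,3,0,0,3
11,5,0,0,0,0,0
12,0,0,1,1,0,0
13,1,0,2,0,0,4
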