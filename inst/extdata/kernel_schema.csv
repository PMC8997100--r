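kernel,rank
SOFT,1
B20f,1
B20s,1
A,1
FC01,1
STANDARD,2
B30f,2
B31f,2
B,2
FC08,2
CHEST,3
B45f,3
B46f,3
C,3
FC18,3
BONE,4
B60f,4
B64f,4
D,4
FC30,4
LUNG,5
EDGE,5
B70f,5
YC,5
FC50,5
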