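"males","females"
0,95
33,0
0,41
34,0
0,37
76,0
40,0
0,70
0,42
0,42
36,0
0,26
0,109
0,64
0,39
44,0
40,0
44,0
13,50
46,0
40,0
37,0
25,25
19,36
16,48
0,52
23,0
26,0
20,41
23,0
39,36
0,48
0,55
0,39
15,0
23,45
19,0
20,46
11,38
0,58
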