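id,recruit_time,event_time,lost_to_followup
1,0,4.61,0
2,0,0.66,0
3,1,3.70,0
4,6,13.51,0
5,7,6.86,0
6,7,12.94,0
7,8,18.71,0
8,11,8.64,0
9,11,0.90,0
10,11,2.91,0
11,20,5.11,0
12,20,0.81,0
13,21,4.85,0
14,22,2.20,0
15,22,15.21,0
16,22,4.77,0
17,24,0.81,0
18,25,13.04,0
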