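subject_id,gender,age,course_months,n_seizures,impaired_flag
1,F,6,0.4,1,FALSE
2,M,7,1.5,2,TRUE
3,M,10,1,2,FALSE
4,F,6,0.9,1,TRUE
5,M,9,3.8,2,TRUE
6,M,9,0.3,1,FALSE
7,F,11,0.6,2,FALSE
8,F,6,1.2,3,TRUE
9,M,10,0.9,1,FALSE
10,M,6,2.1,2,TRUE
11,F,6,0.9,2,FALSE
12,M,7,2.9,3,TRUE
13,F,7,2.5,2,TRUE
14,M,6,0.7,2,FALSE
15,F,8,0.8,2,FALSE
16,M,6,1.4,2,TRUE
17,F,6,0.1,1,FALSE
18,M,7,0.1,1,FALSE
19,M,6,0.2,1,FALSE
20,F,6,3.6,3,TRUE
21,M,7,5.5,3,TRUE
22,F,7,2,3,TRUE
23,F,10,0.3,1,FALSE
24,F,6,2.1,4,TRUE
25,F,7,0.3,1,FALSE
26,M,7,2.2,3,TRUE
27,M,8,0.8,2,FALSE
28,F,8,3.5,5,TRUE
29,M,7,1,1,FALSE
30,F,9,2.7,4,TRUE
31,M,8,0.6,3,FALSE
32,F,11,0.6,2,FALSE
33,M,6,3.1,3,TRUE
34,F,7,3.2,4,TRUE
35,M,10,0.9,2,FALSE
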