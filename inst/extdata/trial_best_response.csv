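patient_id,clinical_stage,best_response
1,T3,PR
2,T3,PR
3,T3,SD
4,T3,SD
5,T3,PR
6,T4,PR
7,T3,SD
8,T3,SD
9,T3,SD
10,T4,SD
11,T3,SD
12,T3,SD
13,T3,PR
14,T3,PR
15,T3,SD
16,T3,SD
17,T3,SD
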