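term,n_any,n_grade3plus
Diarrhea,12,0
Anorexia,10,1
Fatigue,10,2
Hypertension,10,4
Nausea,9,0
Palmar-plantar erythrodysesthesia syndrome,9,5
Mouth sores,8,2
Alanine aminotransferase increased,6,0
Hypomagnesemia,4,0
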