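timepoint,k,n
baseline,4,13
W6D1,6,14
PostTx,5,16
PostSx,1,11
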