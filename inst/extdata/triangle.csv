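study,t1,t2,y,se
s1,A,B,1,1
s2,B,C,1,1
s3,A,C,2,1
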