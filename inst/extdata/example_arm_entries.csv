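trial,entry
1,A
1,B
1,C
1,A
1,C
1,B
1,A
1,B
1,C
2,B
2,A
2,B
2,A
2,C
2,A
2,B
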