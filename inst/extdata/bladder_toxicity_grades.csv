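grade,count
0,118
1,43
2,9
3,4
4,1
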