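# period=24
time
 1
 4
 7
10
13
16
19
22
25
28
31
34
37
40
43
46
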