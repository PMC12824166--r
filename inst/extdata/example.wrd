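0 7040 she
7040 12320 had
12320 21120 your
21120 32240 dark
32240 44800 suit
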