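# balanced 4-cycle example: one alternating cycle, wDCJ distance 1
>g1
1	2	3
3	4	1
>g2
1	3	2
2	4	2
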