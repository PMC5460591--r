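# one circular chromosome: +a (5) -b (7) back to a
>chr1 circular
+a 5 -b 7
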