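A	Sample1	10000
B	Sample2	10000
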