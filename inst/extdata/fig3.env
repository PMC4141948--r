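A__Sample1__1	Sample1	1
A__Sample1__2	Sample1	1
A__Sample1__3	Sample1	1
A__Sample1__4	Sample1	1
B__Sample2__1	Sample2	1
B__Sample2__2	Sample2	1
B__Sample2__3	Sample2	1
B__Sample2__4	Sample2	1
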