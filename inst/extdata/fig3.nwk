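((A__Sample1__1:0,A__Sample1__2:0,A__Sample1__3:0,A__Sample1__4:0)A:0.1,(B__Sample2__1:0,B__Sample2__2:0,B__Sample2__3:0,B__Sample2__4:0)B:0.1);
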