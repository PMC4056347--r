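sample	type
D-01	DGC
D-02	DGC
D-03	DGC
D-04	DGC
D-05	DGC
D-06	DGC
D-07	DGC
D-08	DGC
D-09	DGC
D-10	DGC
D-11	DGC
D-12	DGC
D-13	DGC
D-14	DGC
I-01	IGC
I-02	IGC
I-03	IGC
I-04	IGC
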