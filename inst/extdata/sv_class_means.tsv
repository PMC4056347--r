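type	insertion	deletion	inversion	intra_translocation	inter_translocation
DGC	211	264	27	44	6
IGC	285	283	34	38	24
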