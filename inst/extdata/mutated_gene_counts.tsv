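group	n_genes	n_common
DGC	581	22
IGC	288	22
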