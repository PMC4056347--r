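sample	kind	alteration	region
D-01	CNV	Loss	Exons 1 to 16
D-02	SNV	N256S	Exon 6
D-02	CNV	Loss	Exons 1 to 16
D-03	SNV	Splice site	Donor site of Intron 4
D-04	CNV	Loss	Exons 1 to 16
D-05	SNV	D257N	Exon 6
D-05	INS	S829fs	Exon 16
D-09	SNV	V252G	Exon 6
D-09	SV	Break point	Intron 2
D-10	CNV	Loss	Exons 1 to 16
D-11	CNV	Loss	Exons 1 to 16
D-12	SNV	Q23*	Exon 2
D-13	CNV	Loss	Exons 1 to 16
D-13	SV	Break point	Introns 2 and 10
D-14	SV	Break point	Introns 2, 5 and 9
I-01	CNV	Loss	Exons 1 to 16
I-02	CNV	Loss	Exons 1 to 16
I-03	SNV	D221G	Exon 5
I-03	SV	Break point	Introns 10 and 13
I-04	CNV	Loss	Exons 1 to 16
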