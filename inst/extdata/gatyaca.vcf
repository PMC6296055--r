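##fileformat=VCFv4.2
##INFO=<ID=AF,Number=A,Type=Float,Description="ALT allele frequency">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO
toy	4	snv1	T	C	.	PASS	AF=0.4
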