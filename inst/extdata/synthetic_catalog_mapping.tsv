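# canonical_column	file_column
position	bp
te_family	family
chrom	contig
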