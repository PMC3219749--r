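version	genome_size	n_genes	n_transcripts	n_exons	n_introns
annotVer1.0	243568484	26682	26682	117116	90434
annotVer1.0_mapped	197271687	20923	20923	100721	79798
annotVer2.0	197271687	23248	25600	136008	110408
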