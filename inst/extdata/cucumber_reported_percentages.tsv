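stat	numerator	denominator	printed
multiexon_transcript_or_protein	16270	18580	87.5
multiexon_all_three	12049	18580	64.8
multiexon_denovo_only	2003	18580	10.8
full_length_transcript	13342	18580	71.8
full_length_denovo	10528	18580	56.7
full_length_protein	7447	18580	40.1
complete_orf_transcripts	9964	220590	4.5
specific_hits_v1	684	2595	26.4
specific_hits_v2	3134	5285	59.3
specific_multiexon_v1	1216	2595	46.9
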