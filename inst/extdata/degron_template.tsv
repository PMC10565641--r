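# Template for a validated-degron table (tab-delimited, UTF-8).
# Required columns: substrate_name, window_seq.
# Optional columns: zero_protein_pos (1-based '0' position in the source
# protein), source_ref (free-text citation tag).
# Windows must share one length L and carry S or T in the declared '0' column.
substrate_name	window_seq	zero_protein_pos	source_ref
#EXAMPLE	LLTPQQD	123	PMID:0000000
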