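# Template pipeline configuration for `degscan run --config`.
# Exactly one motif source: motif_pattern OR degron_tsv.
motif_pattern: "[LP][LP][TS]P..[TSDE]"
# degron_tsv: degrons.tsv        # derive the consensus instead
# include_threshold: 0.2
# max_class: 4
proteome_fasta: proteome.fa      # canonical sequences to scan
fasta_dialect: uniprot           # or: plain
phosphosites_tsv: sites.tsv      # optional: protein_id/position/residue TSV
ortholog_dir: families/          # optional: aligned FASTA per gene
gmt:
  - genesets.gmt
venn_set: WNT_SIGNALING_SYN      # optional: set for the overlap counts
# universe: universe.txt         # optional: one symbol per line
conservation_threshold: 0.8
fdr_cut: 0.05
out_dir: degscan_out
seed: 1
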