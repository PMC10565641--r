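WNT_SIGNALING_SYN	synthetic gene set	WNTX1	WNTX2	WNTX3	TFAC1	TFAC2	FZDX1	DSHV1
KINASE_SYN	synthetic gene set	KINB1	KINB2	CDKX1
MEMBRANE_SYN	synthetic gene set	MEMB1	MEMB2	RASL1
HOUSEKEEPING_SYN	synthetic gene set	CYTO1	RASL2	MEMB1	KINB2
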