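protein_id	position	residue
SYN0005	32	T
SYN0005	67	T
SYN0010	42	S
SYN0011	15	S
SYN0012	73	S
SYN0012	93	T
SYN0005	36	S
SYN0001	31	E
SYN0012	68	Y
SYN0006	9	H
SYN0006	82	S
SYN0005	88	T
SYN0003	86	W
SYN0010	32	F
SYN0002	142	T
SYN0006	4	D
SYN0004	78	D
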