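# Synthetic validated-degron catalog (stand-in training windows, NOT curated
# from literature). Windows are aligned on the phospho-acceptor: L = 7,
# '0' column = 3, '+4' column = 7.
substrate_name	window_seq	zero_protein_pos	source_ref
TOYSUB01	LLTPQRD	101	synthetic
TOYSUB02	LPTPSGE	88	synthetic
TOYSUB03	PLSPAQT	230	synthetic
TOYSUB04	LLTPEDS	57	synthetic
TOYSUB05	PLTPGHE	312	synthetic
TOYSUB06	LPSPNLD	144	synthetic
TOYSUB07	LLTPKWT	199	synthetic
TOYSUB08	PPSPVFE	76	synthetic
TOYSUB09	LLTPIYD	410	synthetic
TOYSUB10	PPSPMCS	265	synthetic
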