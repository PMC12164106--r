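statistic	side	pattern
DFO	L	BABA
DFO	L	BBBA
DFO	R	BAAB
DFO	R	BBAB
DIL	L	ABBA
DIL	L	BBBA
DIL	R	ABAB
DIL	R	BBAB
DFI	L	BABA
DFI	L	BABB
DFI	R	ABBA
DFI	R	ABBB
DOL	L	BAAB
DOL	L	BABB
DOL	R	ABAB
DOL	R	ABBB
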