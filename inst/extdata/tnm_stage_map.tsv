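# Simplified colorectal TNM -> stage lookup (editable). Rows are matched in
# order; '*' matches any token; first match wins; no match -> unstaged.
t	n	m	stage
*	*	M1	IV
*	*	M1a	IV
*	*	M1b	IV
*	*	M1c	IV
*	N1	M0	III
*	N1a	M0	III
*	N1b	M0	III
*	N1c	M0	III
*	N2	M0	III
*	N2a	M0	III
*	N2b	M0	III
T1	N0	M0	I
T2	N0	M0	I
T3	N0	M0	II
T4	N0	M0	II
T4a	N0	M0	II
T4b	N0	M0	II
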