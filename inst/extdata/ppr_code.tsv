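# Two-residue PPR recognition code: amino acid at motif position 5 and at
# the motif's last position -> nucleotides the motif preferentially binds.
# Compiled from the published combinatorial codes for P/L/S motifs of
# editing-factor PPR proteins; a replaceable asset, not hard-coded logic.
# Pairs absent here score as non-matching.
aa5	aa_last	nucleotides
T	N	A
T	D	G
S	N	A
S	D	G
N	D	U
N	N	CU
N	S	C
N	T	C
A	D	U
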