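pdb_id	space_group	a	b	c	alpha	beta	gamma	cell_volume	z	asym_mw	verified	note
1trz	H3	80.70	80.70	37.78	90	90	120	213078	9	11920	TRUE	Hexagonal-setting rhombohedral insulin hexamer lattice; cell constants and asymmetric-unit weight (two insulin monomers plus two zinc ions) transcribed from the public database entry summary.
1ev6	P21	61.8	61.6	47.9	90	110.5	90	170807	2	35600	FALSE	Monoclinic hexameric insulin form; the database header was not available when this table was assembled, so cell constants and asymmetric-unit weight are approximate literature-based values for a monoclinic insulin hexamer and are NOT an exact transcription.
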