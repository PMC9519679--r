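kind	sv_type	count
by_type	DEL	183489
by_type	INS	70197
by_type	DUP	93079
by_type	INV	6583
by_type	TRA	105323
singleton	ALL	232071
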