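motif_id	consensus	source	note
ERF	GCCGCC	PLACE-style	GCC box, ethylene response factor binding
GATA	WGATAR	PLACE-style	GATA factor binding core
Dof	AAAG	PLACE-style	Dof zinc-finger core
WRKY	TTGACY	PLACE-style	W-box, WRKY binding
MYB1AT	WAACCA	PLACE-style	MYB/SANT recognition site (dehydration responsive)
ATHook	AATATT	PLACE-style	AT-rich minor-groove AT-hook site
RAV1AAT	CAACA	PLACE-style	RAV1 AAT-box, transcriptional repressor binding
ATHB5ATCORE	CAATNATTG	PLACE-style	HD-Zip ATHB5 core, ABA responsive
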