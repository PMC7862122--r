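ligand_id	receptor_id	score
Cal	IKKB	-8.5
For	IKKB	-8.7
Iso	IKKB	-8.4
Kae	IKKB	-8.4
Que	IKKB	-8.2
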