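circ_id	position	context_9mer	score
circ-PRMT1-1	355	GAGGACAUG	0.59
circ-PRMT1-2	392	GAGGACAUG	0.59
circ-PRMT1-3	334	AGAGACUGG	0.61
circ-PRMT1-3	407	GAGGACAUG	0.60
circ-PRMT1-4	319	AGAGACUGG	0.62
circ-PRMT1-4	392	GAGGACAUG	0.60
circ-PRMT1-5	423	AGAGACUGG	0.61
circ-PRMT1-5	496	GAGGACAUG	0.60
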