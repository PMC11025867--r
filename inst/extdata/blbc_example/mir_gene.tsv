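source	target	source_direction	target_direction
miR-141-5p	AHNAK	up	down
miR-141-5p	PPARG	up	down
miR-141-5p	CAV1	up	down
miR-183-5p	AHNAK	up	down
miR-183-5p	PPARG	up	down
miR-183-5p	CAV1	up	down
miR-183-5p	FGF2	up	down
miR-183-5p	EGR1	up	down
miR-183-5p	TNXB	up	down
miR-183-5p	FOS	up	down
miR-486-5p	CDK1	down	up
miR-486-5p	KIF11	down	up
miR-486-5p	SDC1	down	up
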