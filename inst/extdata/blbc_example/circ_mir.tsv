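source	target	source_direction	target_direction
hsa_circRNA_100435	miR-141-5p	down	up
hsa_circRNA_101004	miR-183-5p	down	up
hsa_circRNA_000585	miR-486-5p	up	down
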