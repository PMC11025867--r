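Published basal-like breast-cancer ceRNA hub network used as a worked
example: three circRNA-miRNA sponge pairs, the miRNA->gene target edges
restricted to the ten BottleNeck hub genes, and the hub gene list.
Joining the two pair tables on the shared miRNA yields the thirteen
circRNA-miRNA-gene regulatory modules.
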