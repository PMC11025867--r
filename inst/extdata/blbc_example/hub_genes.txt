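AHNAK
CAV1
CDK1
EGR1
FGF2
FOS
KIF11
PPARG
SDC1
TNXB
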