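# nonspecific-binder
SHARED_BG
SIM_BEADS_01
SIM_BEADS_02
# keratin
KRT1_SYN
KRT10_SYN
# astrocyte-enriched
AQP4_SYN
GJA1_SYN
SLC1A3_SYN
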