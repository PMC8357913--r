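CC:nucleus	synthetic nuclear term	SIM00001	SIM00002	SIM00003	SIM00004	SIM00005
CC:plasma_membrane	synthetic membrane term	SIM00006	SIM00007	SIM00008
CC:cytosol	synthetic cytosolic term	SIM00009	SIM00010	SIM00011	SIM00012
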