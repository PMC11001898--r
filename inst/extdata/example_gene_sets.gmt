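iron_storage	synthetic example set	FTL	SIG001	SIG002	SIG003	SIG004	SIG005
cellular_senescence	synthetic example set	SIG010	SIG011	SIG012	SIG013	SIG014	SIG015
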