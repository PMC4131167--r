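g001	pp	g004
g001	pp	g010
g002	pp	g005
g004	pp	g010
g005	pp	g006
g005	pp	g007
g009	pp	g010
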