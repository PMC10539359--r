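label	chain_role	first_residue	last_residue
heavy_V173-V188	heavy	173	188
light_T129-F139	light	129	139
light_L47-A51	light	47	51
light_T31-Y36	light	31	36
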