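label	hs_total	e_vdw	e_elec
daridorexant	-44.8	-25.2	-59.6
lemborexant	-39.9	-23.2	-33.1
suvorexant	-43.7	-25.2	-53.0
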