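label	homo_eV	lumo_eV
daridorexant	-6.19316	-1.32595
lemborexant	-6.53966	-1.11510
suvorexant	-5.87751	-1.40361
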