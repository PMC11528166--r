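# BC5CDR categorical relaxation: both types are already broad categories,
# so the mapping is the identity.
Disease	Disease
Chemical	Chemical
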