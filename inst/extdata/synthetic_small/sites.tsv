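chain_id	ligand	positions
syn0001	ZN	4,42,57,71
syn0002	ZN	72
syn0003	ZN	26
syn0004	ZN	36
syn0005	ZN	79
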