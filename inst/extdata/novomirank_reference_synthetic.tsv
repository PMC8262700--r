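feature	mean	sd
precursor_len	70	10
gc_fraction	0.5	0.1
energy_per_nt	-0.8	0.3
mature_len	22	1.5
paired_fraction	0.6	0.15
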