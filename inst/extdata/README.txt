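Synthetic toy fixtures (3 nuclear families, 11 individuals, 3 locations on a
path graph) used by the unit tests and the README example. Generated by hand;
no real data.
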