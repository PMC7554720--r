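# Subcellular-location vocabulary: substring pattern (case-insensitive,
# matched within one comma/semicolon-separated location token) -> collapsed
# compartment. Earlier rows win when several patterns match one token.
pattern	compartment
chloroplast	plastid
plastid	plastid
thylakoid	plastid
mitochondri	mitochondrion
endoplasmic reticulum	endoplasmic reticulum
plasma membrane	membrane
cell membrane	membrane
membrane	membrane
cytoplasm	cytoplasm
cytosol	cytoplasm
nucleus	nucleus
nucleolus	nucleus
vacuole	vacuole
peroxisome	peroxisome
golgi	golgi
secreted	secreted
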